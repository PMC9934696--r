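# internal helpers shared across modules

# standardize to mean 0, sd 1 (n-1 denominator)
std1 <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("Cannot standardize a constant (zero-variance) vector.")
  }
  (x - mean(x)) / s
}

# validate a scored-cohort data frame: id, ps_std, pheno_std
check_scored <- function(data, call = rlang::caller_env()) {
  need <- c("id", "ps_std", "pheno_std")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("`data` is missing required column(s): ",
                 paste(miss, collapse = ", ")), call = call)
  }
  if (anyDuplicated(data$id) > 0) {
    abort("`data$id` contains duplicated identifiers.", call = call)
  }
  if (any(!is.finite(data$ps_std)) || any(!is.finite(data$pheno_std))) {
    abort("`ps_std` and `pheno_std` must be finite (remove missing rows first).",
          call = call)
  }
  invisible(data)
}

# seed handling: all stochastic entry points take an explicit seed
with_seed_if <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a child seed so that independent stochastic stages triggered by one
# user-facing seed do not share streams
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 48271L + as.integer(k)) %% 2147483647L
}
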