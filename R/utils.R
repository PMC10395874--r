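# Internal helpers shared across modules.

logit <- function(p) log(p / (1 - p))

#' Round half away from zero
#'
#' Integer rounding used for score weights: 0.5 rounds to 1, -0.5 to -1
#' (base `round()` rounds half to even, which is not what score derivation
#' needs).
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_away <- function(x) {
  r <- as.integer(sign(x) * floor(abs(x) + 0.5))
  names(r) <- names(x)
  r
}

# Derive a reproducible sub-seed from a master seed and a stream index, so
# that covariates, random intercepts and outcome draws come from independent
# named streams: recalibrating an intercept never perturbs the covariates.
# Kept below 2^31 - 1.
substream <- function(seed, stream) {
  as.integer((as.double(seed) %% 65521 + 1) * 30269 + stream * 7907) %% 2147483587L
}

# Outcome-stratified fold assignment at the episode level. Returns an integer
# vector of fold ids in 1..k. With fold_by = "patient", whole patients are
# assigned to folds (no stratification guarantee).
make_folds <- function(y, k, fold_by = c("episode", "patient"), patient_id = NULL) {
  fold_by <- match.arg(fold_by)
  n <- length(y)
  folds <- integer(n)
  if (fold_by == "episode") {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    stopifnot(!is.null(patient_id))
    pats <- unique(patient_id)
    pf <- sample(rep_len(seq_len(k), length(pats)))
    folds <- pf[match(patient_id, pats)]
  }
  folds
}

`%||%` <- function(a, b) if (is.null(a)) b else a
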