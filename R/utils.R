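#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from one master seed through named
#' substreams, so that e.g. changing the number of permutations does not
#' perturb the simulation draws.  The derivation is a fixed integer hash of
#' the master seed, a stream label and an optional index; the result is
#' always a valid 32-bit seed.
#'
#' @param seed Integer master seed.
#' @param label Character stream label (e.g. `"permutation"`).
#' @param index Optional non-negative integer, for per-replicate streams.
#' @return An integer seed in `[0, 2^31)`.
#' @examples
#' derive_seed(1L, "permutation")
#' derive_seed(1L, "simulate", 7)
#' @export
derive_seed <- function(seed, label, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  val <- (abs(as.numeric(seed)) %% 2147483647) * 48271 + h * 7919 +
    as.numeric(index) * 104729
  as.integer(val %% 2147483629)
}

# Run `code` under a fixed seed without disturbing the caller's RNG state.
# A NULL seed leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Internal canonical representation of a case-control genotype dataset:
# list(geno = N x M integer matrix in {0,1,2}, pheno = integer 0/1,
#      snps = character labels, ids = character subject ids).
as_geno <- function(data, class_column = "Class", id_column = NULL) {
  if (inherits(data, "geno_internal")) return(data)
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data)
  if (!class_column %in% names(data)) {
    abort(sprintf("class column '%s' not found", class_column))
  }
  if (!is.null(id_column)) {
    if (!id_column %in% names(data)) {
      abort(sprintf("id column '%s' not found", id_column))
    }
    ids <- as.character(data[[id_column]])
    data[[id_column]] <- NULL
  } else {
    ids <- sprintf("S%04d", seq_len(nrow(data)))
  }
  pheno <- data[[class_column]]
  data[[class_column]] <- NULL
  if (is.logical(pheno)) pheno <- as.integer(pheno)
  if (!all(pheno %in% c(0, 1))) {
    abort("phenotype must be binary 0/1 (1 = case)")
  }
  pheno <- as.integer(pheno)
  if (length(unique(pheno)) < 2L) {
    abort("phenotype must contain at least one case and one control")
  }
  geno <- as.matrix(data)
  if (!is.numeric(geno)) {
    bad <- which(!vapply(data, is.numeric, logical(1)))
    abort(sprintf(
      "non-numeric genotype column(s): %s",
      paste(names(data)[bad], collapse = ", ")
    ))
  }
  storage.mode(geno) <- "integer"
  bad <- which(!(geno %in% c(0L, 1L, 2L)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(geno))
    abort(sprintf(
      "invalid genotype code %s at row %d, column '%s' (codes must be 0/1/2)",
      geno[bad[1]], rc[1], colnames(geno)[rc[2]]
    ))
  }
  if (anyNA(geno)) abort("missing genotype codes are not allowed here")
  structure(
    list(geno = geno, pheno = pheno, snps = colnames(geno), ids = ids),
    class = "geno_internal"
  )
}

# Order-statistic empirical CDF: fraction of samples <= x (vectorised in x).
ecdf_value <- function(samples, x) {
  stopifnot(length(samples) > 0)
  findInterval(x, sort(samples)) / length(samples)
}

# Order-statistic inverse CDF: inf{ x : ecdf(x) >= p }.  For p = 0 this
# infimum is -Inf over the reals; over the sample support we return the
# minimum sample, which is the only finite choice consistent with clamping.
quantile_inf <- function(samples, p) {
  stopifnot(length(samples) > 0, all(p >= 0 & p <= 1))
  s <- sort(samples)
  # the epsilon keeps p = k/n from rounding up to the (k+1)-th order statistic
  s[pmax(1L, ceiling(p * length(s) - 1e-9))]
}
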