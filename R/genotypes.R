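#' Genotype container
#'
#' Bundles an individuals-by-loci allele-dosage matrix (values 0, 1, 2 or
#' `NA`) with per-individual metadata. Dosage counts copies of the
#' alternate allele; hemizygous females at Z-linked loci are stored as
#' homozygous (0 or 2), the way diploid genotype callers emit them.
#'
#' @param dosage numeric matrix, individuals in rows (rownames = ids),
#'   loci in columns (colnames = locus ids), entries in `{0, 1, 2, NA}`.
#' @param meta data frame with one row per individual; must contain an
#'   `id` column matching `rownames(dosage)`. Typical columns: `species`,
#'   `plot`, `year`, `stage` ("adult"/"nestling"), `sex` ("M"/"F"/NA).
#' @return An object of class `genotypes`.
#' @export
genotypes <- function(dosage, meta = NULL) {
  if (!is.matrix(dosage)) abort("`dosage` must be a matrix")
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    abort("`dosage` needs individual ids as rownames and locus ids as colnames")
  if (anyDuplicated(rownames(dosage))) abort("duplicate individual ids")
  if (anyDuplicated(colnames(dosage))) abort("duplicate locus ids")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) abort("dosage values must be 0, 1, 2 or NA")
  if (nrow(dosage) < 2 || ncol(dosage) < 2)
    abort("need at least 2 individuals and 2 loci")
  if (is.null(meta)) meta <- tibble(id = rownames(dosage))
  meta <- as_tibble(meta)
  if (!"id" %in% names(meta)) abort("`meta` must have an `id` column")
  if (!setequal(meta$id, rownames(dosage)))
    abort("`meta$id` must match rownames(dosage)")
  meta <- meta[match(rownames(dosage), meta$id), ]
  structure(list(dosage = dosage, meta = meta), class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf(
    "<genotypes> %d individuals x %d loci (%.1f%% missing)\n",
    nrow(x$dosage), ncol(x$dosage), 100 * mean(is.na(x$dosage))
  ))
  invisible(x)
}

#' @export
dim.genotypes <- function(x) dim(x$dosage)

#' Subset a genotypes object by individual and/or locus
#'
#' @param g a [genotypes] object.
#' @param ids individual ids (or logical/integer index) to keep.
#' @param loci locus ids (or logical/integer index) to keep.
#' @return A [genotypes] object.
#' @export
subset_genotypes <- function(g, ids = NULL, loci = NULL) {
  stopifnot(inherits(g, "genotypes"))
  d <- g$dosage
  if (!is.null(ids)) d <- d[ids, , drop = FALSE]
  if (!is.null(loci)) d <- d[, loci, drop = FALSE]
  genotypes(d, g$meta[g$meta$id %in% rownames(d), ])
}

#' Iterative call-rate filter
#'
#' Removes individuals, then loci, whose non-missing fraction falls below
#' `threshold`, repeating both passes until no further removal occurs.
#' Removing an individual can rescue a locus (and vice versa), so a single
#' pass is order-dependent; the fixed point is not.
#'
#' @param g a [genotypes] object.
#' @param threshold minimum call rate in `(0, 1]` (default 0.7).
#' @return Filtered [genotypes] with a `call_rate_report` attribute: a
#'   tibble listing each removed individual/locus, its call rate and the
#'   pass on which it was dropped.
#' @export
filter_call_rate <- function(g, threshold = 0.7) {
  stopifnot(inherits(g, "genotypes"))
  if (!(threshold > 0 && threshold <= 1)) abort("`threshold` must be in (0, 1]")
  d <- g$dosage
  report <- list()
  pass <- 0L
  repeat {
    pass <- pass + 1L
    changed <- FALSE
    cr_ind <- rowMeans(!is.na(d))
    drop_i <- cr_ind < threshold
    if (any(drop_i)) {
      report[[length(report) + 1L]] <- tibble(
        what = "individual", id = rownames(d)[drop_i],
        call_rate = unname(cr_ind[drop_i]), pass = pass
      )
      d <- d[!drop_i, , drop = FALSE]
      changed <- TRUE
    }
    if (nrow(d) == 0)
      abort(sprintf("call-rate filter at %.2f removed every individual", threshold))
    cr_loc <- colMeans(!is.na(d))
    drop_l <- cr_loc < threshold
    if (any(drop_l)) {
      report[[length(report) + 1L]] <- tibble(
        what = "locus", id = colnames(d)[drop_l],
        call_rate = unname(cr_loc[drop_l]), pass = pass
      )
      d <- d[, !drop_l, drop = FALSE]
      changed <- TRUE
    }
    if (!changed) break
  }
  out <- genotypes(d, g$meta[g$meta$id %in% rownames(d), ])
  attr(out, "call_rate_report") <-
    if (length(report)) bind_rows(report) else
      tibble(what = character(), id = character(),
             call_rate = double(), pass = integer())
  out
}

#' Per-locus alternate-allele frequencies
#'
#' `p_k` is the dosage sum at locus `k` over non-missing individuals,
#' divided by twice the non-missing count.
#'
#' @param g a [genotypes] object.
#' @return Tibble with `locus`, `p`, `n_called` and a `monomorphic` flag
#'   (`p` exactly 0 or 1).
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotypes"))
  d <- g$dosage
  n_called <- colSums(!is.na(d))
  if (any(n_called == 0))
    abort(sprintf(
      "locus with zero non-missing calls: %s",
      paste(head(colnames(d)[n_called == 0], 5), collapse = ", ")
    ))
  p <- colSums(d, na.rm = TRUE) / (2 * n_called)
  tibble(
    locus = colnames(d), p = unname(p), n_called = unname(n_called),
    monomorphic = p == 0 | p == 1
  )
}

#' Genomic relatedness matrix (GCTA estimator)
#'
#' Realized-relatedness estimates from standardized allele dosages. For
#' individuals \eqn{j \neq k},
#' \deqn{G_{jk} = \frac{1}{m_{jk}} \sum_{l}
#'   \frac{(x_{jl} - 2p_l)(x_{kl} - 2p_l)}{2 p_l (1 - p_l)},}
#' summing over the \eqn{m_{jk}} loci called in both individuals
#' (pairwise-complete, no imputation), and
#' \deqn{G_{jj} = 1 + \frac{1}{m_j} \sum_l
#'   \frac{x_{jl}^2 - (1 + 2p_l) x_{jl} + 2 p_l^2}{2 p_l (1 - p_l)}.}
#' Frequencies come from [allele_frequencies()] on the full post-QC sample
#' (adults and nestlings pooled). Monomorphic and near-monomorphic loci
#' (`p < 1/(2n)` or `p > 1 - 1/(2n)`) are dropped first.
#'
#' @param g a [genotypes] object after QC.
#' @param freqs optional precomputed output of [allele_frequencies()];
#'   computed from `g` when `NULL`.
#' @return A `grm` object: list with `r` (symmetric relatedness matrix),
#'   `n_loci` (pairwise shared-locus counts) and `ids`. Pairs sharing zero
#'   loci get `NA` and are listed in the `zero_overlap` attribute.
#' @export
grm_gcta <- function(g, freqs = NULL) {
  stopifnot(inherits(g, "genotypes"))
  if (nrow(g$dosage) < 2) abort("need at least 2 individuals")
  if (is.null(freqs)) freqs <- allele_frequencies(g)
  n <- nrow(g$dosage)
  eps <- 1 / (2 * n)
  keep <- freqs$p >= eps & freqs$p <= 1 - eps
  if (!any(keep)) abort("no polymorphic loci left for the GRM")
  d <- g$dosage[, keep, drop = FALSE]
  p <- freqs$p[keep]
  w <- 2 * p * (1 - p)

  called <- !is.na(d)
  s <- sweep(d, 2, 2 * p)              # x - 2p
  s <- sweep(s, 2, sqrt(w), "/")
  s[!called] <- 0
  num <- tcrossprod(s)
  m <- tcrossprod(called * 1)
  r <- num / m                          # NaN where m == 0
  r[m == 0] <- NA_real_

  # diagonal uses its own per-locus form
  dd <- sweep(d^2 - sweep(d, 2, 1 + 2 * p, "*"), 2, 2 * p^2, "+")
  dd <- sweep(dd, 2, w, "/")
  dd[!called] <- 0
  mj <- rowSums(called)
  diag(r) <- 1 + rowSums(dd) / mj
  diag(m) <- mj

  ids <- rownames(d)
  dimnames(r) <- dimnames(m) <- list(ids, ids)
  zero <- which(m == 0 & upper.tri(m), arr.ind = TRUE)
  out <- structure(list(r = r, n_loci = m, ids = ids), class = "grm")
  attr(out, "zero_overlap") <- tibble(
    id1 = ids[zero[, 1]], id2 = ids[zero[, 2]]
  )
  attr(out, "n_loci_used") <- sum(keep)
  out
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf(
    "<grm> %d individuals, %d loci used\n",
    length(x$ids), attr(x, "n_loci_used") %||% NA_integer_
  ))
  invisible(x)
}

#' Long-format view of a relatedness matrix
#'
#' @param x a `grm` object (or any square matrix of class `grm` layout).
#' @param upper_only keep each unordered pair once (default `TRUE`).
#' @return Tibble `id1`, `id2`, `relatedness`, `n_loci`.
#' @export
grm_tidy <- function(x, upper_only = TRUE) {
  stopifnot(inherits(x, "grm"))
  idx <- which(if (upper_only) upper.tri(x$r) else row(x$r) != col(x$r),
               arr.ind = TRUE)
  tibble(
    id1 = x$ids[idx[, 1]], id2 = x$ids[idx[, 2]],
    relatedness = x$r[idx], n_loci = x$n_loci[idx]
  )
}
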