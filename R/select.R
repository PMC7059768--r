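# Entropy-based IMF selection and signal rebuild.
#
# Each IMF is scored by the entropy-style cost
#   e_i = -sum_k u_k log(u_k),   u_k = ||gamma_i(t_k)||^2,
# the per-sample squared Euclidean norm across channels, with the
# convention 0 log 0 = 0 and the natural logarithm.  The formula is
# energy-weighted and therefore scale-dependent: ranking IMFs of the
# same decomposition is meaningful, comparing across signals of
# different overall amplitude is not.  For ranking, all IMFs can be
# placed on a common scale by dividing the squared norms by the total
# energy of the decomposition (a single shared factor, so the formula
# itself is unchanged); this makes the selection invariant to the units
# of the recording and is the default.

#' Entropy cost of a single IMF
#'
#' @param imf numeric vector (single channel) or p x T matrix (one
#'   p-variate IMF, channels in rows).
#' @return scalar: `-sum(u * log(u))` over per-sample squared norms `u`,
#'   with `0 * log(0) = 0` and natural logarithm; no normalization.
#' @examples
#' imf_entropy(matrix(0, 2, 10))                  # 0
#' u <- c(0.5, 0.5)
#' imf_entropy(sqrt(u))                           # log(2)
#' @export
imf_entropy <- function(imf) {
  m <- if (is.matrix(imf)) imf else matrix(imf, nrow = 1L)
  if (!all(is.finite(m))) stop("IMF values must be finite")
  u <- colSums(m^2)
  u <- u[u > 0]
  if (!length(u)) return(0)
  -sum(u * log(u))
}

.imfset_matrices <- function(imfset) {
  if (inherits(imfset, "mimf_set")) return(imfset$imfs)
  if (inherits(imfset, "imf_set"))
    return(lapply(imfset$imfs, function(v) matrix(v, nrow = 1L)))
  stop("expected an imf_set or mimf_set")
}

#' Entropy of every IMF in a decomposition
#'
#' @param imfset an `imf_set` or `mimf_set`.
#' @param normalize if `TRUE` (default) the squared norms of all IMFs are
#'   divided by one common factor, the total energy of the decomposition
#'   (sum of IMFs plus residual), before applying the entropy formula.
#'   `FALSE` gives the raw, scale-dependent values.
#' @return numeric vector of entropies, one per IMF, with attribute
#'   `order`: IMF indices sorted by decreasing entropy (ties broken by
#'   ascending index).
#' @export
imf_entropies <- function(imfset, normalize = TRUE) {
  mats <- .imfset_matrices(imfset)
  if (!length(mats)) return(structure(numeric(0), order = integer(0)))
  scale <- 1
  if (normalize) {
    res <- if (inherits(imfset, "mimf_set")) imfset$residual else
      matrix(imfset$residual, nrow = 1L)
    etot <- sum(vapply(mats, function(m) sum(m^2), numeric(1L))) + sum(res^2)
    if (etot > 0) scale <- etot
  }
  e <- vapply(mats, function(m) imf_entropy(m / sqrt(scale)), numeric(1L))
  structure(e, order = order(-e, seq_along(e)))
}

#' Select the top-k IMFs by entropy
#'
#' @param imfset an `imf_set` or `mimf_set`.
#' @param k number of modes to keep, `1 <= k <= N`.
#' @param normalize see [imf_entropies()].
#' @return list of class `imf_selection`: `selected` (sorted indices of
#'   the k highest-entropy IMFs), `order` (all indices by decreasing
#'   entropy), `entropies`, `k`.
#' @export
rank_and_select <- function(imfset, k = 3L, normalize = TRUE) {
  e <- imf_entropies(imfset, normalize = normalize)
  N <- length(e)
  if (N == 0L) stop("decomposition has no IMFs")
  k <- as.integer(k)
  if (k < 1L || k > N) stop("k must be between 1 and the IMF count (", N, ")")
  ord <- attr(e, "order")
  structure(list(selected = sort(ord[seq_len(k)]), order = ord,
                 entropies = as.numeric(e), k = k),
            class = "imf_selection")
}

#' @export
print.imf_selection <- function(x, ...) {
  cat("<imf_selection> kept IMFs:", paste(x$selected, collapse = ", "), "\n")
  cat(" entropies:", paste(sprintf("%.4g", x$entropies), collapse = ", "), "\n")
  invisible(x)
}

#' Rebuild a signal from selected IMFs
#'
#' Sums the chosen IMFs only; the residual trend is always excluded.
#'
#' @param imfset an `imf_set` or `mimf_set`.
#' @param selection an `imf_selection` from [rank_and_select()], or an
#'   integer vector of IMF indices (e.g. `c(2, 4, 6)` to reproduce a
#'   hand-picked set).
#' @return an `eeg_signal` for multivariate input, a numeric vector for
#'   univariate input.
#' @export
rebuild <- function(imfset, selection) {
  idx <- if (inherits(selection, "imf_selection")) selection$selected
         else as.integer(selection)
  mats <- .imfset_matrices(imfset)
  if (!length(idx)) stop("selection must keep at least one IMF")
  if (any(idx < 1L | idx > length(mats)))
    stop("selection indices out of range")
  if (anyDuplicated(idx)) stop("duplicated IMF indices in selection")
  out <- Reduce(`+`, mats[idx])
  if (inherits(imfset, "imf_set")) return(drop(out))
  eeg_signal(out, fs = imfset$fs,
             labels = if (!is.null(imfset$labels)) imfset$labels)
}
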