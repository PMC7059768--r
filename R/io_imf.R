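# Serialization of IMF sets: one delimited matrix per IMF plus a YAML
# metadata sidecar.

#' Write / read an IMF decomposition as delimited text
#'
#' Files `<prefix>_imf<k>.tsv` (p x T, tab-separated), `<prefix>_residual.tsv`
#' and `<prefix>_meta.yaml` (sampling rate, mode count, stoppage
#' settings, direction count for multivariate sets, channel labels).
#'
#' @param imfset an `imf_set` or `mimf_set`.
#' @param prefix path prefix.
#' @return `write_imfs` the prefix invisibly; `read_imfs` the
#'   reconstructed object.
#' @export
write_imfs <- function(imfset, prefix) {
  multiv <- inherits(imfset, "mimf_set")
  if (!multiv && !inherits(imfset, "imf_set"))
    stop("expected an imf_set or mimf_set")
  mats <- .imfset_matrices(imfset)
  res <- if (multiv) imfset$residual else matrix(imfset$residual, nrow = 1L)
  for (k in seq_along(mats))
    utils::write.table(mats[[k]], sprintf("%s_imf%02d.tsv", prefix, k),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  utils::write.table(res, paste0(prefix, "_residual.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  meta <- list(type = if (multiv) "mimf_set" else "imf_set",
               fs = imfset$fs, n_imfs = length(mats),
               p = nrow(res), T = ncol(res))
  if (multiv) {
    meta$V <- imfset$config$V
    meta$max_imfs <- imfset$config$max_imfs
    meta$stoppage <- unclass(imfset$config$stoppage)
    meta$labels <- imfset$labels
  } else {
    meta$stoppage <- unclass(imfset$stoppage)
  }
  yaml::write_yaml(meta, paste0(prefix, "_meta.yaml"))
  invisible(prefix)
}

#' @rdname write_imfs
#' @export
read_imfs <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, "_meta.yaml"))
  rd <- function(f) as.matrix(utils::read.table(f, sep = "\t"))
  mats <- lapply(seq_len(meta$n_imfs),
                 function(k) unname(rd(sprintf("%s_imf%02d.tsv", prefix, k))))
  res <- unname(rd(paste0(prefix, "_residual.tsv")))
  stp <- do.call(stoppage_config, meta$stoppage)
  if (identical(meta$type, "mimf_set")) {
    cfg <- memd_config(V = meta$V, stoppage = stp,
                       max_imfs = if (is.null(meta$max_imfs)) 12L else meta$max_imfs)
    new_mimf_set(mats, res, meta$fs, cfg,
                 if (is.null(meta$labels)) NULL else unlist(meta$labels))
  } else {
    new_imf_set(lapply(mats, drop), drop(res), meta$fs, stp)
  }
}
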