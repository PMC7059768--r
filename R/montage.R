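# Idealized spherical 10-10 electrode layout and packaged montages.
#
# Positions are generated by the 10-20 construction on a unit sphere:
# the midline chain runs along the nasion-inion meridian at 10% steps,
# the outer chain lies on the circle through Fpz/T7/Oz/T8 (inclination
# 72 degrees from the vertex) at 18-degree azimuth steps, and interior
# electrodes are placed by spherical interpolation between the midline
# and outer-chain electrode of their row.  This is an idealization of
# the physical 10-10 system adequate for spherical head models; it is
# not a digitized cap.

.slerp <- function(a, b, t) {
  w <- acos(min(max(sum(a * b), -1), 1))
  if (w < 1e-12) return(a)
  (sin((1 - t) * w) * a + sin(t * w) * b) / sin(w)
}

# midline position at fraction f of the nasion-inion arc
.midline_vec <- function(f) c(0, cos(f * pi), sin(f * pi))

# outer-chain position at azimuth psi (radians) from the front;
# side = -1 left, +1 right; inclination 72 degrees from the vertex
.circle_vec <- function(psi, side) {
  incl <- 72 * pi / 180
  c(side * sin(incl) * sin(psi), sin(incl) * cos(psi), cos(incl))
}

.ten_ten_table <- function() {
  rows <- list(Fp = 0.1, AF = 0.2, F = 0.3, FC = 0.4, C = 0.5,
               CP = 0.6, P = 0.7, PO = 0.8, O = 0.9)
  circle <- list(Fp = 18, AF = 36, F = 54, FC = 72, C = 90,
                 CP = 108, P = 126, PO = 144, O = 162)
  circle_name <- list(Fp = "Fp", AF = "AF7", F = "F7", FC = "FT7",
                      C = "T7", CP = "TP7", P = "P7", PO = "PO7", O = "O1")
  pos <- list()
  add <- function(label, v) pos[[label]] <<- v / sqrt(sum(v^2))
  for (r in names(rows)) add(paste0(r, "z"), .midline_vec(rows[[r]]))
  for (r in names(rows)) {
    psi <- circle[[r]] * pi / 180
    lab_l <- circle_name[[r]]
    lab_r <- chartr("17", "28", lab_l)
    if (r == "Fp") { lab_l <- "Fp1"; lab_r <- "Fp2" }
    add(lab_l, .circle_vec(psi, -1))
    add(lab_r, .circle_vec(psi, +1))
  }
  interior <- list(AF = c(3), F = c(1, 3, 5), FC = c(1, 3, 5),
                   C = c(1, 3, 5), CP = c(1, 3, 5), P = c(1, 3, 5),
                   PO = c(3))
  for (r in names(interior)) {
    vm <- .midline_vec(rows[[r]])
    psi <- circle[[r]] * pi / 180
    for (num in interior[[r]]) {
      t <- (num + 1) / 8            # 1 -> 0.25, 3 -> 0.5, 5 -> 0.75
      add(paste0(r, num), .slerp(vm, .circle_vec(psi, -1), t))
      add(paste0(r, num + 1), .slerp(vm, .circle_vec(psi, +1), t))
    }
  }
  pos
}

.ten_ten_cache <- new.env(parent = emptyenv())

#' 10-10 system electrode positions on the unit sphere
#'
#' @param labels character vector of 10-10 labels, or `NULL` for the
#'   full supported set (61 positions).
#' @return numeric matrix, one unit row vector per label (columns x =
#'   right, y = anterior, z = superior), with the labels as row names.
#' @export
ten_ten_positions <- function(labels = NULL) {
  if (is.null(.ten_ten_cache$tab)) .ten_ten_cache$tab <- .ten_ten_table()
  tab <- .ten_ten_cache$tab
  if (is.null(labels)) labels <- names(tab)
  unknown <- setdiff(labels, names(tab))
  if (length(unknown))
    stop("unsupported 10-10 label(s): ", paste(unknown, collapse = ", "))
  out <- t(vapply(tab[labels], identity, numeric(3L)))
  colnames(out) <- c("x", "y", "z")
  out
}

#' Packaged channel-reduction montages
#'
#' Ordered 10-10 label lists for the 8-, 16- and 32-electrode montages
#' used in channel-reduction studies, chosen to keep quasi-uniform
#' scalp coverage, plus the full supported layout (`"full"`, 61
#' channels).  The reduced subsets approximate published low-density
#' layouts; they are a design choice of this package, not a digitized
#' standard.
#'
#' @param n one of 8, 16, 32 or `"full"`.
#' @return character vector of channel labels.
#' @export
montage_labels <- function(n = 32) {
  key <- as.character(n)
  switch(key,
    "8" = c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2"),
    "16" = c("Fp1", "Fp2", "F7", "F3", "F4", "F8", "T7", "C3", "C4",
             "T8", "P7", "P3", "P4", "P8", "O1", "O2"),
    "32" = c("Fp1", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8",
             "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
             "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
             "PO3", "PO4", "O1", "Oz", "O2"),
    "full" = names(.ten_ten_table()),
    stop("supported montages: 8, 16, 32, \"full\"")
  )
}
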