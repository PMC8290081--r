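# Channel montage: the 62-electrode scalp set (standard 64-electrode 10-20
# cap minus CB1/CB2, mastoids included) plus the two bipolar EOG derivations.
# Positions are schematic 2D head coordinates (x: left -1 .. right +1,
# y: posterior -1 .. anterior +1), sufficient for neighbor graphs and
# topography export; they are not digitized electrode locations.

.montage_rows <- list(
  Fp = 0.95, AF = 0.75, F = 0.55, FC = 0.28, C = 0.00,
  CP = -0.28, P = -0.55, PO = -0.75, O = -0.92
)

.montage_def <- local({
  rows <- list(
    c("Fp1", "Fpz", "Fp2"),
    c("AF3", "AF4"),
    c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
    c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
    c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
    c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
    c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
    c("PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8"),
    c("O1", "Oz", "O2")
  )
  ys <- unlist(.montage_rows)
  lab <- character(0); x <- numeric(0); y <- numeric(0)
  xpos <- function(l) {
    # digit suffix: odd = left, even = right, z = midline; scaled to [-0.9, 0.9]
    d <- sub("^[A-Za-z]+", "", l)
    if (d == "" || tolower(substr(l, nchar(l), nchar(l))) == "z") return(0)
    n <- as.integer(d)
    s <- if (n %% 2 == 1) -1 else 1
    s * min(0.9, ceiling(n / 2) * 0.225)
  }
  for (i in seq_along(rows)) {
    for (l in rows[[i]]) {
      lab <- c(lab, l); x <- c(x, xpos(l)); y <- c(y, ys[i])
    }
  }
  # mastoids sit low behind the ears
  lab <- c(lab, "M1", "M2"); x <- c(x, -1.0, 1.0); y <- c(y, -0.40, -0.40)
  kind <- rep("scalp", length(lab))
  kind[lab %in% c("M1", "M2")] <- "mastoid"
  lab <- c(lab, "VEOG", "HEOG"); x <- c(x, -0.35, 0); y <- c(y, 1.1, 1.15)
  kind <- c(kind, "eog", "eog")
  data.frame(label = lab, x = x, y = y, kind = kind,
             stringsAsFactors = FALSE)
})

#' Standard recording montage
#'
#' Returns the channel table used throughout the package: 60 modeling scalp
#' electrodes of the international 10-20 64-channel cap, the two mastoids
#' (M1, M2), and the vertical/horizontal EOG derivations, with schematic 2D
#' positions and a channel kind (`"scalp"`, `"mastoid"`, `"eog"`).
#'
#' @param labels optional character vector restricting (and ordering) the
#'   returned rows; unknown labels raise an error.
#' @return data.frame with columns `label`, `x`, `y`, `kind`.
#' @export
standard_montage <- function(labels = NULL) {
  m <- .montage_def
  if (is.null(labels)) return(m)
  idx <- match(labels, m$label)
  if (anyNA(idx)) {
    stop("unknown channel label(s): ",
         paste(labels[is.na(idx)], collapse = ", "))
  }
  m[idx, , drop = FALSE]
}

#' The 60 modeling channels
#'
#' Channel labels used for classifier construction: the standard cap minus
#' CB1/CB2 and minus the mastoid and EOG channels.
#'
#' @return character vector of 60 labels.
#' @export
model60_labels <- function() {
  m <- .montage_def
  m$label[m$kind == "scalp"]
}

#' Channel neighbor graph
#'
#' Builds a symmetric adjacency matrix over channels from the montage's 2D
#' positions using mutual proximity: each channel is linked to its `k`
#' nearest neighbors and the relation is symmetrized (union).  EOG channels
#' are never linked to scalp channels.
#'
#' @param labels channel labels (must exist in [standard_montage()]).
#' @param k number of nearest neighbors per channel.
#' @return logical matrix `length(labels) x length(labels)`, `FALSE` on the
#'   diagonal.
#' @export
montage_adjacency <- function(labels, k = 4) {
  m <- standard_montage(labels)
  n <- nrow(m)
  adj <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  if (n <= 1) return(adj)
  d <- as.matrix(stats::dist(cbind(m$x, m$y)))
  diag(d) <- Inf
  for (i in seq_len(n)) {
    ord <- order(d[i, ])[seq_len(min(k, n - 1))]
    adj[i, ord] <- TRUE
  }
  adj <- adj | t(adj)
  eog <- m$kind == "eog"
  adj[eog, !eog] <- FALSE
  adj[!eog, eog] <- FALSE
  diag(adj) <- FALSE
  adj
}

#' Read electrode positions from an .sfp-style file
#'
#' Plain-text file with one electrode per line: `label x y [z]`,
#' whitespace-separated.
#'
#' @param path file path.
#' @return data.frame with columns `label`, `x`, `y` (and `z` if present).
#' @export
read_sfp <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("expected at least 3 columns: label x y")
  names(tab)[1:3] <- c("label", "x", "y")
  if (ncol(tab) >= 4) names(tab)[4] <- "z"
  tab
}
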