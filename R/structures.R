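#' Construct a charged structural model
#'
#' A `charged_model` is the package's basic container for a set of labeled
#' sites (C-alpha atoms or coarse beads) with Cartesian coordinates in
#' Angstrom and per-site partial charges in elementary-charge units.  It is a
#' `data.frame` with columns `site_id`, `resid`, `resname`, `chain`, `x`,
#' `y`, `z`, `charge`, `class`.
#'
#' Coordinates follow one fixed convention throughout the package:
#' right-handed Cartesian axes in Angstrom, the filament axis along +z, and
#' azimuth measured counter-clockwise when looking down +z.
#'
#' @param df data.frame with at least `resid`, `x`, `y`, `z`.  Missing
#'   `site_id` is filled with the row number, missing `resname`/`chain`/
#'   `class` with placeholders, missing `charge` with 0.
#' @return a `charged_model` data.frame.
#' @export
charged_model <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("resid", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("charged_model: missing required column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(df$site_id)) df$site_id <- seq_len(nrow(df))
  if (is.null(df$resname)) df$resname <- "BEA"
  if (is.null(df$chain)) df$chain <- "A"
  if (is.null(df$charge)) df$charge <- 0
  if (is.null(df$class)) df$class <- "CA"
  df <- df[, c("site_id", "resid", "resname", "chain", "x", "y", "z", "charge", "class")]
  df$site_id <- as.integer(df$site_id)
  df$resid <- as.integer(df$resid)
  validate_charged_model(df)
  class(df) <- c("charged_model", "data.frame")
  df
}

validate_charged_model <- function(df) {
  if (any(df$resid < 1L)) stop("charged_model: residue_index must be >= 1")
  xyz <- as.matrix(df[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("charged_model: non-finite coordinates")
  key <- paste(df$chain, df$resid, df$site_id)
  if (anyDuplicated(key)) {
    stop("charged_model: duplicate (chain, resid, site_id) key: ",
         key[duplicated(key)][1])
  }
  invisible(df)
}

#' @export
print.charged_model <- function(x, ...) {
  cat(sprintf("charged_model: %d sites, %d residues, net charge %+0.2f e\n",
              nrow(x), length(unique(paste(x$chain, x$resid))), sum(x$charge)))
  NextMethod()
}

#' Coordinates of a charged model as an N x 3 matrix
#' @param model a `charged_model`
#' @return numeric matrix with columns x, y, z
#' @export
coords <- function(model) {
  as.matrix(model[, c("x", "y", "z")])
}

set_coords <- function(model, xyz) {
  model$x <- xyz[, 1]
  model$y <- xyz[, 2]
  model$z <- xyz[, 3]
  model
}

#' Construct a trajectory
#'
#' A `trajectory` stores an ordered sequence of frames over a fixed site set.
#' Coordinates live in an `n_frames x 3N` matrix (frame rows; columns
#' x1,y1,z1,x2,...), the layout used by structural-bioinformatics packages
#' for trajectory math.
#'
#' @param xyz numeric matrix, `n_frames x 3N`.
#' @param sites `charged_model` (or plain data.frame) describing the N sites,
#'   in column order.
#' @param time optional per-frame time labels (ns).
#' @return a `trajectory` object.
#' @export
trajectory <- function(xyz, sites, time = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) %% 3L != 0L) stop("trajectory: xyz must have 3N columns")
  n <- ncol(xyz) / 3L
  if (nrow(sites) != n) {
    stop(sprintf("trajectory: sites (%d) do not match coordinate columns (%d sites)",
                 nrow(sites), n))
  }
  if (!all(is.finite(xyz))) stop("trajectory: non-finite coordinates")
  if (!is.null(time) && length(time) != nrow(xyz)) {
    stop("trajectory: time labels must match frame count")
  }
  structure(list(xyz = xyz, sites = sites, time = time), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d sites\n", n_frames(x), n_sites(x)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Number of sites in a trajectory
#' @param traj a `trajectory`
#' @export
n_sites <- function(traj) ncol(traj$xyz) / 3L

#' Coordinates of one frame as an N x 3 matrix
#' @param traj a `trajectory`
#' @param i frame index (1-based)
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Flatten an N x 3 coordinate matrix to a 3N vector (x1,y1,z1,x2,...)
#' @keywords internal
flatten_coords <- function(m) as.numeric(t(m))

#' Require at least `n` frames for a dynamics operation
#' @keywords internal
require_frames <- function(traj, n = 2L, what = "dynamics analysis") {
  if (n_frames(traj) < n) {
    stop(sprintf("%s requires >= %d frames (got %d)", what, n, n_frames(traj)))
  }
  invisible(traj)
}

#' Select site indices of a trajectory
#'
#' @param traj a `trajectory`
#' @param selection `NULL` (all sites), an integer vector of site indices,
#'   a logical vector, or an integer vector of residue numbers given as
#'   `list(resid = ...)`.
#' @return integer site indices
#' @export
select_sites <- function(traj, selection = NULL) {
  n <- n_sites(traj)
  if (is.null(selection)) return(seq_len(n))
  if (is.list(selection) && !is.null(selection$resid)) {
    idx <- which(traj$sites$resid %in% selection$resid)
  } else if (is.logical(selection)) {
    stopifnot(length(selection) == n)
    idx <- which(selection)
  } else {
    idx <- as.integer(selection)
    stopifnot(all(idx >= 1L & idx <= n))
  }
  if (!length(idx)) stop("selection is empty")
  idx
}

#' Column indices into the 3N coordinate matrix for given site indices
#' @keywords internal
xyz_cols <- function(site_idx) {
  as.vector(rbind(3L * site_idx - 2L, 3L * site_idx - 1L, 3L * site_idx))
}
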