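#' Read a structural model (PDB or delimited bead table)
#'
#' PDB files are parsed with \pkg{bio3d} (ATOM/HETATM records only; the
#' multi-model and header chemistry subsets of the format are out of scope
#' here).  Delimited tables must carry a header with at least `resid`, `x`,
#' `y`, `z`; a `charge` column is honored directly.
#'
#' Charge sources for PDB input:
#' \describe{
#'   \item{`"none"`}{all charges 0 (default).}
#'   \item{`"bfactor"`}{charges read from the B-factor column (PDB has no
#'     charge field; this is the packing convention used by the writer).}
#'   \item{`"residue-table"`}{side-chain formal charges by residue name:
#'     ASP/GLU -1, LYS/ARG +1, all others 0 (termini ignored).}
#'   \item{`"table"`}{sidecar table (data.frame or CSV path) with columns
#'     `site_id`, `charge`.}
#' }
#'
#' @param path file path
#' @param charge_source one of `"none"`, `"bfactor"`, `"residue-table"`,
#'   `"table"`
#' @param charge_table sidecar charge table (for `charge_source = "table"`)
#' @return a [charged_model()]
#' @export
read_structure <- function(path,
                           charge_source = c("none", "bfactor", "residue-table", "table"),
                           charge_table = NULL) {
  charge_source <- match.arg(charge_source)
  if (!file.exists(path)) stop("read_structure: file not found: ", path)
  if (is_pdb_path(path)) {
    check_pdb_lines(path)
    pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                    error = function(e) stop("read_structure: PDB parse error in ",
                                             path, ": ", conditionMessage(e)))
    at <- pdb$atom
    df <- data.frame(site_id = at$eleno,
                     resid = at$resno,
                     resname = at$resid,
                     chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
                     x = at$x, y = at$y, z = at$z,
                     class = at$elety,
                     stringsAsFactors = FALSE)
    df$charge <- switch(charge_source,
                        "none" = 0,
                        "bfactor" = at$b,
                        "residue-table" = residue_formal_charge(df$resname),
                        "table" = lookup_charge_table(df$site_id, charge_table))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          sep = guess_sep(path))
    if (charge_source == "residue-table" && !is.null(df$resname)) {
      df$charge <- residue_formal_charge(df$resname)
    } else if (charge_source == "table") {
      df$charge <- lookup_charge_table(df$site_id, charge_table)
    }
  }
  charged_model(df)
}

#' Formal side-chain charge by residue name
#'
#' ASP/GLU carry -1, LYS/ARG +1, everything else 0.  Termini and histidine
#' protonation states are ignored: the electrostatic landscape machinery is
#' driven by the dominant side-chain charges.
#'
#' @param resname character vector of 3-letter residue codes
#' @return numeric charges (e)
#' @export
residue_formal_charge <- function(resname) {
  ch <- rep(0, length(resname))
  ch[toupper(resname) %in% c("ASP", "GLU")] <- -1
  ch[toupper(resname) %in% c("LYS", "ARG")] <- +1
  ch
}

lookup_charge_table <- function(site_id, charge_table) {
  if (is.null(charge_table)) stop("charge_source='table' requires charge_table")
  if (is.character(charge_table)) {
    charge_table <- utils::read.csv(charge_table, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("site_id", "charge") %in% names(charge_table)))
  idx <- match(site_id, charge_table$site_id)
  if (anyNA(idx)) {
    stop("charge table missing site_id(s): ",
         paste(site_id[is.na(idx)][1:min(3, sum(is.na(idx)))], collapse = ", "))
  }
  charge_table$charge[idx]
}

is_pdb_path <- function(path) grepl("\\.(pdb|ent)$", path, ignore.case = TRUE)

guess_sep <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

# Cheap format validation so malformed ATOM records are reported with their
# line number (the downstream parser's messages do not carry one).
check_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  atom <- grepl("^(ATOM|HETATM)", lines)
  for (i in which(atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop(sprintf("read_structure: malformed ATOM record at line %d (too short)", i))
    }
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords)))) {
      stop(sprintf("read_structure: malformed ATOM record at line %d (bad coordinates)", i))
    }
  }
  invisible(TRUE)
}

#' Read a trajectory (multi-model PDB or per-frame XYZ table)
#'
#' Multi-model PDB files (MODEL/ENDMDL blocks) are read with \pkg{bio3d}.
#' XYZ tables are delimited files with header `frame, site_id, x, y, z`
#' (0-based or 1-based frame indices both accepted; ordering is by first
#' appearance).  Every frame must contain the same sites in the same order.
#'
#' @param path file path
#' @return a [trajectory()]
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("read_trajectory: file not found: ", path)
  if (is_pdb_path(path)) {
    check_pdb_lines(path)
    check_model_blocks(path)
    pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                    error = function(e) stop("read_trajectory: PDB parse error in ",
                                             path, ": ", conditionMessage(e)))
    at <- pdb$atom
    sites <- charged_model(data.frame(site_id = at$eleno,
                                      resid = at$resno,
                                      resname = at$resid,
                                      chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
                                      x = at$x, y = at$y, z = at$z,
                                      charge = at$b,
                                      class = at$elety,
                                      stringsAsFactors = FALSE))
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    trajectory(unclass(xyz)[, , drop = FALSE], sites)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, sep = guess_sep(path))
    stopifnot(all(c("frame", "site_id", "x", "y", "z") %in% names(df)))
    frames <- unique(df$frame)
    split_f <- split(df, factor(df$frame, levels = frames))
    n0 <- nrow(split_f[[1]])
    for (k in seq_along(split_f)) {
      if (nrow(split_f[[k]]) != n0) {
        stop(sprintf("read_trajectory: frame %s has %d sites, expected %d",
                     frames[k], nrow(split_f[[k]]), n0))
      }
      if (!identical(split_f[[k]]$site_id, split_f[[1]]$site_id)) {
        stop(sprintf("read_trajectory: frame %s has different site ordering", frames[k]))
      }
    }
    f1 <- split_f[[1]]
    sites <- charged_model(data.frame(site_id = f1$site_id,
                                      resid = if (!is.null(f1$resid)) f1$resid else f1$site_id,
                                      x = f1$x, y = f1$y, z = f1$z,
                                      stringsAsFactors = FALSE))
    xyz <- t(vapply(split_f,
                    function(fr) flatten_coords(as.matrix(fr[, c("x", "y", "z")])),
                    numeric(3L * n0)))
    trajectory(xyz, sites)
  }
}

check_model_blocks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  if (!length(model_starts)) return(invisible(TRUE))
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts)) {
    stop("read_trajectory: unbalanced MODEL/ENDMDL records")
  }
  counts <- mapply(function(s, e) sum(grepl("^(ATOM|HETATM)", lines[s:e])),
                   model_starts, model_ends)
  if (length(unique(counts)) > 1L) {
    bad <- which(counts != counts[1])[1]
    stop(sprintf("read_trajectory: frame %d has %d sites, expected %d",
                 bad, counts[bad], counts[1]))
  }
  invisible(TRUE)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Emits the minimal ATOM/MODEL/ENDMDL subset with per-site charge stored in
#' the B-factor column (8.3f coordinate precision, so round-trips agree to
#' 1e-3 A).
#'
#' @param traj a [trajectory()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path) {
  s <- traj$sites
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    m <- frame_coords(traj, f)
    writeLines(sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                       s$site_id %% 100000L, substr(s$class, 1, 4),
                       substr(s$resname, 1, 3), substr(s$chain, 1, 1),
                       s$resid %% 10000L, m[, 1], m[, 2], m[, 3],
                       1.0, s$charge), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a structural model as a single-model PDB file
#'
#' @param model a [charged_model()]
#' @param path output path
#' @param charge_in_bfactor store charges in the B-factor column (default TRUE)
#' @return `path`, invisibly
#' @export
write_structure <- function(model, path, charge_in_bfactor = TRUE) {
  b <- if (charge_in_bfactor) model$charge else rep(0, nrow(model))
  lines <- sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                   model$site_id %% 100000L, substr(model$class, 1, 4),
                   substr(model$resname, 1, 3), substr(model$chain, 1, 1),
                   model$resid %% 10000L, model$x, model$y, model$z, 1.0, b)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a 2D grid (energy landscape or free-energy surface) to disk
#'
#' Delimited matrix with the column axis as header and the row axis as first
#' column, preceded by `#`-prefixed metadata lines (axis units, contour
#' specification, any generator metadata).  Cell values are written in full
#' precision; the round-trip through [read_grid()] is exact to 1e-6.
#'
#' @param x an `energy_landscape` or `fes` object, or a plain list with
#'   `row_axis`, `col_axis`, `values` (matrix), and optional `meta`.
#' @param path output path
#' @param allow_na allow missing cells (used for free-energy surfaces where
#'   unobserved bins are genuinely missing); energy landscapes must be
#'   complete.
#' @return `path`, invisibly
#' @export
write_grid <- function(x, path, allow_na = inherits(x, "fes")) {
  g <- as_grid(x)
  if (!allow_na && anyNA(g$values)) {
    bad <- which(is.na(g$values), arr.ind = TRUE)
    lab <- apply(bad, 1, function(ij)
      sprintf("(%g, %g)", g$row_axis[ij[1]], g$col_axis[ij[2]]))
    stop("write_grid: grid has missing cells at: ",
         paste(utils::head(lab, 5), collapse = ", "))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# row_axis: %s", g$row_label), con)
  writeLines(sprintf("# col_axis: %s", g$col_label), con)
  for (nm in names(g$meta)) {
    writeLines(sprintf("# %s: %s", nm, paste(g$meta[[nm]], collapse = " ")), con)
  }
  tab <- cbind(g$row_axis, g$values)
  colnames(tab) <- c("axis", format(g$col_axis, trim = TRUE))
  utils::write.table(format(tab, digits = 12, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

as_grid <- function(x) {
  if (inherits(x, "energy_landscape")) {
    list(row_axis = x$azimuth, col_axis = x$z, values = x$energy,
         row_label = "azimuth (deg)", col_label = "z offset (A)",
         meta = c(list(contours = x$contour_levels), x$meta))
  } else if (inherits(x, "fes")) {
    if (is.matrix(x$pmf)) {
      list(row_axis = x$axis1, col_axis = x$axis2, values = x$pmf,
           row_label = "PC1 (bin centers)", col_label = "PC2 (bin centers)",
           meta = list(temperature_K = x$temperature_K, bin_size = x$bin_size))
    } else {
      list(row_axis = x$axis1, col_axis = 0, values = cbind(x$pmf),
           row_label = "PC1 (bin centers)", col_label = "profile",
           meta = list(temperature_K = x$temperature_K, bin_size = x$bin_size))
    }
  } else {
    stopifnot(is.list(x), !is.null(x$values))
    x$row_label <- x$row_label %||% "row"
    x$col_label <- x$col_label %||% "col"
    x$meta <- x$meta %||% list()
    x
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a grid written by [write_grid()]
#'
#' @param path file path
#' @return list with `row_axis`, `col_axis`, `values` matrix and `meta`
#'   (named character metadata from the `#` header lines)
#' @export
read_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- sub("^[^:]*:\\s*", "", kv)
  }
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           check.names = FALSE)
  list(row_axis = tab[[1]],
       col_axis = as.numeric(sub("^X", "", names(tab)[-1])),
       values = unname(as.matrix(tab[, -1, drop = FALSE])),
       meta = meta)
}

#' Write the generation metadata sidecar of a synthetic artifact
#'
#' Every generator in the package attaches its full specification and seed
#' as a `"meta"` attribute; this writes that record as JSON next to the data
#' so each artifact is reproducible from its sidecar alone.
#'
#' @param x object carrying a `"meta"` attribute
#' @param path output path (JSON)
#' @return `path`, invisibly
#' @export
write_metadata <- function(x, path) {
  meta <- attr(x, "meta")
  if (is.null(meta)) stop("write_metadata: object has no metadata attribute")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
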