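#' Read structure frames from PDB input
#'
#' Parses a multi-model PDB file (or a directory of single-frame PDB files,
#' taken in lexicographic order) into a tidy atom table, one row per atom per
#' frame. Only fixed-column `ATOM`/`HETATM` records are consumed; `MODEL` /
#' `ENDMDL` records delimit frames. Author residue numbering and chain
#' identifiers are kept verbatim.
#'
#' Alternate locations: only the blank or first-listed (`"A"`) conformer is
#' kept, so selections are deterministic. Residues carrying an insertion code
#' are dropped.
#'
#' @param path Path to a PDB file, or to a directory containing `*.pdb` files
#'   (one frame each).
#' @param format One of `"auto"` (default: directory vs file is detected),
#'   `"multi-model-pdb"`, or `"pdb-directory"`.
#' @return A tibble with columns `frame` (integer, 1-based), `time_ps`
#'   (numeric, `NA` when the file carries no time information), `atom_name`,
#'   `residue_name`, `residue_number`, `chain_id`, `x`, `y`, `z` (Å).
#' @seealso [write_pdb_frames()], [select_ca()]
#' @examples
#' spec <- dimer_geometry(angle_deg = 10, n_frames = 2)
#' path <- tempfile(fileext = ".pdb")
#' dim <- make_dimer(spec)
#' write_pdb_frames(dim$atoms, path)
#' frames <- read_pdb_frames(path)
#' dplyr::count(frames, frame)
#' @export
read_pdb_frames <- function(path, format = c("auto", "multi-model-pdb", "pdb-directory")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("cannot read structure input: '", path, "' does not exist"))
  }
  is_dir <- dir.exists(path)
  if (format == "auto") format <- if (is_dir) "pdb-directory" else "multi-model-pdb"

  if (format == "pdb-directory") {
    files <- sort(list.files(path, pattern = "\\.pdb$", full.names = TRUE))
    if (length(files) == 0L) {
      abort(paste0("no .pdb files found in directory '", path, "'"))
    }
    frames <- purrr::imap(files, function(f, i) {
      atoms <- parse_pdb_lines(readLines(f, warn = FALSE), source = f)
      if (length(unique(atoms$frame)) > 1L) {
        abort(paste0("file '", f, "' in a pdb-directory input contains multiple MODELs"))
      }
      dplyr::mutate(atoms, frame = as.integer(i))
    })
    out <- dplyr::bind_rows(frames)
  } else {
    out <- parse_pdb_lines(readLines(path, warn = FALSE), source = path)
  }
  check_frame_consistency(out)
  out
}

# Parse ATOM/HETATM records using the fixed PDB columns; MODEL increments the
# frame counter. Returns atoms of frame 1 when no MODEL records are present.
parse_pdb_lines <- function(lines, source = "<input>") {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_idx <- cumsum(startsWith(lines, "MODEL"))
  if (!any(is_atom)) {
    abort(paste0("no ATOM records found in '", source, "'"))
  }
  al <- lines[is_atom]
  frame <- model_idx[is_atom]
  if (all(frame == 0L)) frame <- frame + 1L

  altloc <- substr(al, 17, 17)
  icode <- substr(al, 27, 27)
  keep <- altloc %in% c(" ", "A") & icode == " "

  xs <- suppressWarnings(as.numeric(substr(al, 31, 38)))
  ys <- suppressWarnings(as.numeric(substr(al, 39, 46)))
  zs <- suppressWarnings(as.numeric(substr(al, 47, 54)))
  resno <- suppressWarnings(as.integer(substr(al, 23, 26)))
  bad <- which(keep & (is.na(xs) | is.na(ys) | is.na(zs) | is.na(resno)))
  if (length(bad) > 0L) {
    abort(paste0("malformed ATOM record in '", source, "' (record ", bad[1], ")"))
  }

  tibble::tibble(
    frame = as.integer(frame[keep]),
    time_ps = NA_real_,
    atom_name = trimws(substr(al, 13, 16))[keep],
    residue_name = trimws(substr(al, 18, 20))[keep],
    residue_number = resno[keep],
    chain_id = substr(al, 22, 22)[keep],
    x = xs[keep], y = ys[keep], z = zs[keep]
  )
}

# All frames of one trajectory must contain the same atom set, in the same
# order; name the first offending frame otherwise.
check_frame_consistency <- function(atoms) {
  ids <- split(
    paste(atoms$chain_id, atoms$residue_number, atoms$atom_name),
    atoms$frame
  )
  if (length(ids) < 2L) return(invisible(atoms))
  ref <- ids[[1L]]
  for (k in seq_along(ids)[-1L]) {
    if (!identical(ids[[k]], ref)) {
      abort(paste0(
        "structural inconsistency: frame ", names(ids)[k],
        " does not contain the same atom set as frame ", names(ids)[1L]
      ))
    }
  }
  invisible(atoms)
}

#' Write an atom table as a multi-model PDB file
#'
#' Inverse of [read_pdb_frames()] for the atom-table layout used throughout
#' the package. Coordinates are written in the fixed 8.3 PDB columns, i.e.
#' quantized to 0.001 Å; round-tripping reproduces coordinates to that
#' precision only.
#'
#' @param atoms Atom tibble as returned by [read_pdb_frames()] or
#'   [make_dimer()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_frames <- function(atoms, path) {
  stopifnot(is.data.frame(atoms), all(c("frame", "atom_name", "residue_number",
    "chain_id", "x", "y", "z") %in% names(atoms)))
  resname <- if ("residue_name" %in% names(atoms)) atoms$residue_name else rep("GLY", nrow(atoms))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in sort(unique(atoms$frame))) {
    sel <- atoms$frame == f
    n <- sum(sel)
    writeLines(sprintf("MODEL     %4d", f), con)
    name4 <- ifelse(nchar(atoms$atom_name[sel]) < 4L,
      sprintf(" %-3s", atoms$atom_name[sel]), atoms$atom_name[sel])
    writeLines(sprintf(
      "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %1s",
      seq_len(n), name4, resname[sel], atoms$chain_id[sel],
      atoms$residue_number[sel], atoms$x[sel], atoms$y[sel], atoms$z[sel],
      substr(trimws(atoms$atom_name[sel]), 1, 1)
    ), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Residue selection for the interface secondary-structure elements
#'
#' Bundles the chain identifiers of the two LBD subunits with the author
#' residue ranges of the three interface elements: the small helix S, the
#' large helix L, and the central beta-sheet C (two strands). Defaults are the
#' GluA2 LBD numbering: S = 606-610, L = 742-756, C = 617-622 plus 727-732.
#'
#' @param chain_a,chain_b Single-character chain identifiers of the two
#'   subunits.
#' @param s_range,l_range Inclusive residue intervals, length-2 integer
#'   vectors.
#' @param c_ranges List of inclusive residue intervals for the sheet strands.
#' @return An object of class `selection_spec`.
#' @export
selection_spec <- function(chain_a = "A", chain_b = "B",
                           s_range = c(606L, 610L),
                           l_range = c(742L, 756L),
                           c_ranges = list(c(617L, 622L), c(727L, 732L))) {
  check_range <- function(r, what) {
    if (length(r) != 2L || any(!is.finite(r)) || r[2] < r[1]) {
      abort(paste0("invalid ", what, " residue interval: must be c(lo, hi) with hi >= lo"))
    }
    as.integer(r)
  }
  if (!is.list(c_ranges)) c_ranges <- list(c_ranges)
  structure(
    list(
      chain_a = as.character(chain_a), chain_b = as.character(chain_b),
      s_range = check_range(s_range, "S"),
      l_range = check_range(l_range, "L"),
      c_ranges = lapply(c_ranges, check_range, what = "C")
    ),
    class = "selection_spec"
  )
}

#' @export
print.selection_spec <- function(x, ...) {
  fmt <- function(r) paste0(r[1], "-", r[2])
  cat("<selection_spec>\n",
    "  chains: A='", x$chain_a, "'  B='", x$chain_b, "'\n",
    "  S helix:  ", fmt(x$s_range), "\n",
    "  L helix:  ", fmt(x$l_range), "\n",
    "  C sheet:  ", paste(vapply(x$c_ranges, fmt, ""), collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Read a flat key-value selection config
#'
#' Reads `key: value` lines (comments with `#`) into a [selection_spec()].
#' Recognised keys: `chain_a`, `chain_b`, `s_range`, `l_range`, `c_ranges`
#' (ranges written as `lo-hi`, several separated by commas), and optional
#' window parameters `window_ps`, `interval_ps` returned as attributes.
#'
#' @param path Path to the config file.
#' @return A `selection_spec`, possibly with attributes `window_ps` and
#'   `interval_ps`.
#' @export
read_selection_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- stringr::str_match(lines, "^([A-Za-z_]+)\\s*:\\s*(.+)$")
  if (any(is.na(kv[, 1]))) {
    abort(paste0("malformed config line: '", lines[which(is.na(kv[, 1]))[1]], "'"))
  }
  vals <- setNames(trimws(kv[, 3]), kv[, 2])
  parse_range <- function(s) as.integer(strsplit(s, "-", fixed = TRUE)[[1]])
  args <- list()
  if (!is.na(vals["chain_a"])) args$chain_a <- unname(vals["chain_a"])
  if (!is.na(vals["chain_b"])) args$chain_b <- unname(vals["chain_b"])
  if (!is.na(vals["s_range"])) args$s_range <- parse_range(vals["s_range"])
  if (!is.na(vals["l_range"])) args$l_range <- parse_range(vals["l_range"])
  if (!is.na(vals["c_ranges"])) {
    args$c_ranges <- lapply(strsplit(vals["c_ranges"], ",")[[1]], function(s) parse_range(trimws(s)))
  }
  spec <- do.call(selection_spec, args)
  if (!is.na(vals["window_ps"])) attr(spec, "window_ps") <- as.numeric(vals["window_ps"])
  if (!is.na(vals["interval_ps"])) attr(spec, "interval_ps") <- as.numeric(vals["interval_ps"])
  spec
}

#' Select C-alpha coordinates for a residue range on one chain
#'
#' Extracts the positions of atoms named `"CA"` whose author residue number
#' falls in any of the given inclusive intervals on the given chain, ordered
#' by residue number. Residues missing from the structure shrink the
#' selection with a warning; an empty selection is an error (silent shrinkage
#' to nothing must be visible).
#'
#' @param atoms Atom tibble for a **single** frame.
#' @param chain Single-character chain id.
#' @param ranges A length-2 inclusive interval `c(lo, hi)` or a list of them.
#' @return A numeric matrix with one row per selected residue (rownames are
#'   residue numbers) and columns `x`, `y`, `z`.
#' @examples
#' dim <- make_dimer(dimer_geometry())
#' s_pts <- select_ca(dim$atoms, "A", c(606, 610))
#' nrow(s_pts) # 5
#' @export
select_ca <- function(atoms, chain, ranges) {
  if (!is.list(ranges)) ranges <- list(ranges)
  if (length(unique(atoms$frame)) > 1L) {
    abort("select_ca() operates on a single frame; filter the atom table first")
  }
  wanted <- sort(unique(unlist(lapply(ranges, function(r) seq(r[1], r[2])))))
  hit <- atoms$atom_name == "CA" & atoms$chain_id == chain &
    atoms$residue_number %in% wanted
  sel <- atoms[hit, , drop = FALSE]
  sel <- sel[order(sel$residue_number), , drop = FALSE]
  rng_txt <- paste(vapply(ranges, function(r) paste0(r[1], "-", r[2]), ""), collapse = ",")
  if (nrow(sel) == 0L) {
    abort(paste0("empty selection: no CA atoms on chain '", chain,
      "' in residue range ", rng_txt))
  }
  if (nrow(sel) < length(wanted)) {
    warn(paste0("selection on chain '", chain, "', range ", rng_txt, ": only ",
      nrow(sel), " of ", length(wanted), " residues present"))
  }
  m <- as.matrix(sel[, c("x", "y", "z")])
  rownames(m) <- sel$residue_number
  m
}
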