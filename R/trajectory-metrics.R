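#' Per-frame descriptor series for a trajectory
#'
#' Applies [compute_descriptors()] to every frame of an atom table, using the
#' residue selection in `sel` to locate the S/L/C elements of both subunits.
#'
#' @param atoms Atom tibble covering one or more frames, as from
#'   [read_pdb_frames()] or [make_dimer()].
#' @param sel A [selection_spec()].
#' @return A tibble with columns `frame`, `time_ps` and the eight descriptor
#'   columns, one row per frame, in frame order.
#' @examples
#' dim <- make_dimer(dimer_geometry(angle_deg = 15, n_frames = 3, jitter_sd = 0.05))
#' descriptor_series(dim$atoms, selection_spec())
#' @export
descriptor_series <- function(atoms, sel = selection_spec()) {
  frames <- sort(unique(atoms$frame))
  rows <- purrr::map(frames, function(f) {
    fa <- atoms[atoms$frame == f, , drop = FALSE]
    res <- tryCatch(
      {
        planes <- interface_frames_from_atoms(fa, sel)
        compute_descriptors(planes$a, planes$b)
      },
      error = function(e) {
        abort(paste0("descriptor computation failed at frame ", f, ": ",
          conditionMessage(e)))
      }
    )
    t <- fa$time_ps[1]
    dplyr::bind_cols(tibble::tibble(frame = f, time_ps = t), res)
  })
  dplyr::bind_rows(rows)
}

#' Average descriptors over the stable trajectory window
#'
#' Arithmetic mean of each descriptor over the frames whose time stamp lies
#' in `[t_end - window_length_ps, t_end]`. With the defaults (20 ns window,
#' 200 ps frame interval) exactly 101 frames are averaged, matching the usual
#' "last 20 ns" stable-portion convention. When the series carries no time
#' stamps, the last `expected_frames` frames are used instead.
#'
#' @param series Descriptor series tibble from [descriptor_series()].
#' @param window_length_ps Window length in ps (default 20000 = 20 ns).
#' @param frame_interval_ps Expected frame spacing in ps (default 200); used
#'   only to derive `expected_frames` when that is `NULL`.
#' @param expected_frames Number of frames the window should contain
#'   (default `window_length_ps / frame_interval_ps + 1` = 101). A mismatch
#'   triggers a warning; averaging proceeds over the frames available.
#' @return A one-row tibble of the eight averaged descriptors, with
#'   attributes `n_frames` (frames averaged) and `window_ps`.
#' @export
window_average <- function(series, window_length_ps = 20000,
                           frame_interval_ps = 200,
                           expected_frames = NULL) {
  if (nrow(series) == 0L) abort("window_average(): empty descriptor series")
  if (is.null(expected_frames)) {
    expected_frames <- as.integer(round(window_length_ps / frame_interval_ps) + 1L)
  }
  has_time <- !all(is.na(series$time_ps))
  if (has_time) {
    t_end <- max(series$time_ps, na.rm = TRUE)
    inwin <- !is.na(series$time_ps) &
      series$time_ps >= t_end - window_length_ps - 1e-9 &
      series$time_ps <= t_end + 1e-9
    win <- series[inwin, , drop = FALSE]
  } else {
    win <- tail(series[order(series$frame), , drop = FALSE], expected_frames)
  }
  if (nrow(win) == 0L) abort("window_average(): no frames fall inside the window")
  if (nrow(win) != expected_frames) {
    warn(paste0("window_average(): ", nrow(win), " frames in window, expected ",
      expected_frames, "; averaging over the frames available"))
  }
  out <- dplyr::summarise(win, dplyr::across(dplyr::all_of(descriptor_names()), mean))
  attr(out, "n_frames") <- nrow(win)
  attr(out, "window_ps") <- window_length_ps
  out
}

#' RMSD quality-control traces for a trajectory
#'
#' Least-squares superposes every frame onto the first frame (optimal
#' rotation + translation over the fit selection, Kabsch algorithm) and
#' reports the RMSD of each named report group per frame. The default fit set
#' is the protein C-alpha atoms and the default report group is all heavy
#' (non-hydrogen) atoms, the usual stability readout for an MD trajectory.
#'
#' @param atoms Atom tibble covering at least two frames.
#' @param fit_selection Predicate `function(atoms_one_frame) -> logical`
#'   choosing the atoms used for superposition. Default: atoms named `"CA"`.
#' @param report_groups Named list of predicates choosing each reported
#'   group's atoms. Default: `list(protein = <heavy atoms>)`.
#' @return Tibble with columns `frame`, `time_ps`, `group`, `rmsd` (Å). The
#'   first frame's RMSD is 0 for every group.
#' @export
rmsd_trace <- function(atoms,
                       fit_selection = function(a) a$atom_name == "CA",
                       report_groups = list(protein = is_heavy_atom)) {
  frames <- sort(unique(atoms$frame))
  if (length(frames) < 2L) abort("rmsd_trace() needs at least 2 frames")
  if (is.null(names(report_groups)) || any(!nzchar(names(report_groups)))) {
    abort("report_groups must be a named list of predicates")
  }
  ref <- atoms[atoms$frame == frames[1], , drop = FALSE]
  fit_idx <- which(fit_selection(ref))
  if (length(fit_idx) == 0L) abort("rmsd_trace(): empty fit selection")
  grp_idx <- lapply(report_groups, function(p) which(p(ref)))
  empty <- names(grp_idx)[vapply(grp_idx, length, 1L) == 0L]
  if (length(empty) > 0L) {
    abort(paste0("rmsd_trace(): report group '", empty[1], "' selects no atoms"))
  }
  ref_xyz <- as.matrix(ref[, c("x", "y", "z")])

  rows <- purrr::map(frames, function(f) {
    cur <- atoms[atoms$frame == f, , drop = FALSE]
    xyz <- as.matrix(cur[, c("x", "y", "z")])
    fitted <- kabsch_superpose(xyz, ref_xyz, fit_idx)
    tibble::tibble(
      frame = f,
      time_ps = cur$time_ps[1],
      group = names(grp_idx),
      rmsd = unname(vapply(grp_idx, function(ix) {
        sqrt(mean(rowSums((fitted[ix, , drop = FALSE] - ref_xyz[ix, , drop = FALSE])^2)))
      }, numeric(1)))
    )
  })
  dplyr::bind_rows(rows)
}

#' Heavy-atom predicate
#'
#' `TRUE` for atoms whose name does not denote hydrogen (names starting with
#' `H`, or digit-prefixed hydrogens like `1HB`).
#' @param atoms Atom tibble.
#' @return Logical vector.
#' @export
is_heavy_atom <- function(atoms) {
  !grepl("^[0-9]*H", atoms$atom_name)
}

# Optimal superposition of `mobile` onto `target` fitted on rows `fit_idx`;
# returns the whole mobile coordinate set transformed. SVD with a determinant
# guard against reflections (Kabsch).
kabsch_superpose <- function(mobile, target, fit_idx) {
  mf <- mobile[fit_idx, , drop = FALSE]
  tf <- target[fit_idx, , drop = FALSE]
  mc <- colMeans(mf)
  tc <- colMeans(tf)
  h <- t(sweep(mf, 2, mc)) %*% sweep(tf, 2, tc)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(sweep(mobile, 2, mc) %*% t(rot), 2, tc, `+`)
}

#' Line plot of RMSD traces
#'
#' @param trace Output of [rmsd_trace()].
#' @return A ggplot object (RMSD vs time or frame, one line per group).
#' @export
plot_rmsd_trace <- function(trace) {
  has_time <- !all(is.na(trace$time_ps))
  xvar <- if (has_time) "time_ps" else "frame"
  xlab <- if (has_time) "time (ps)" else "frame"
  ggplot2::ggplot(trace, ggplot2::aes(.data[[xvar]], .data$rmsd, colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = "RMSD (Å)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Faceted plot of a descriptor series
#'
#' @param series Output of [descriptor_series()].
#' @return A ggplot object, one facet per descriptor.
#' @export
plot_descriptor_series <- function(series) {
  long <- tidyr::pivot_longer(series, dplyr::all_of(descriptor_names()),
    names_to = "descriptor", values_to = "value")
  long$descriptor <- factor(long$descriptor, levels = descriptor_names())
  has_time <- !all(is.na(series$time_ps))
  xvar <- if (has_time) "time_ps" else "frame"
  ggplot2::ggplot(long, ggplot2::aes(.data[[xvar]], .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~descriptor, scales = "free_y") +
    ggplot2::labs(x = if (has_time) "time (ps)" else "frame", y = NULL) +
    ggplot2::theme_minimal()
}

#' Write a descriptor series or average as TSV
#'
#' One row per frame: `time_ps` plus the eight descriptors, 6 significant
#' digits, header naming the descriptors.
#'
#' @param series Descriptor series or one-row window average.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_descriptor_tsv <- function(series, path) {
  out <- dplyr::mutate(series, dplyr::across(dplyr::where(is.numeric), ~ signif(.x, 6)))
  readr::write_tsv(out, path)
  invisible(path)
}
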