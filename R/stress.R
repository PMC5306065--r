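#' Element ids of a reporting region
#'
#' Maps the three reported anatomical zones to element sets of the levator
#' mesh: \code{"ICm"} is the iliococcygeus label (upper dorsal portion);
#' \code{"pubic_attachment"} is the pubovisceral + puborectal elements whose
#' reference centroid lies within \code{attach_dist} of the pubic attachment
#' node set on the requested side (left by default, x > 0 on the left);
#' \code{"posteromedial_PRm"} is the puborectal elements in the posterior
#' half of the sling (reference centroid dorsal to the hiatal centre).
#'
#' @param mesh a \code{labeled_tet_mesh}.
#' @param region one of "ICm", "pubic_attachment", "posteromedial_PRm", or a
#'   raw label "PVm"/"PRm".
#' @param side "left", "right" or "both" (pubic attachment zone only).
#' @param attach_dist distance defining the attachment zone, mm.
#' @return integer vector of element ids.
#' @export
region_elements <- function(mesh, region, side = "left", attach_dist = 25) {
  cent <- (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
             mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
  out <- switch(region,
    ICm = which(mesh$region == "ICm"),
    PVm = which(mesh$region == "PVm"),
    PRm = which(mesh$region == "PRm"),
    pubic_attachment = {
      pub <- mesh$nodes[mesh$sets$pubic_attachment, , drop = FALSE]
      pub <- switch(side,
                    left = pub[pub[, 1] >= 0, , drop = FALSE],
                    right = pub[pub[, 1] <= 0, , drop = FALSE],
                    both = pub)
      cand <- which(mesh$region %in% c("PVm", "PRm"))
      keep <- vapply(cand, function(e) {
        d2 <- min(colSums((t(pub) - cent[e, ])^2))
        d2 <= attach_dist^2
      }, logical(1))
      cand[keep]
    },
    posteromedial_PRm = {
      y_h <- if (!is.null(mesh$hiatus_dims)) 25 else 0
      which(mesh$region == "PRm" & cent[, 2] < y_h)
    },
    stop(errorCondition(sprintf("unknown region '%s'", region),
                        class = c("levatorfem_lookup_error", "error", "condition"))))
  if (length(out) == 0L)
    stop(errorCondition(sprintf("region '%s' selects no elements", region),
                        class = c("levatorfem_lookup_error", "error", "condition")))
  out
}

#' Regional von Mises summary for one equilibrium state
#'
#' Volume-weighted statistics of element von Mises stress over a region:
#' weighted mean, plain min and max, and volume-weighted population SD.
#'
#' @param state one element of \code{delivery_fem$states} (or any list with
#'   a \code{vm} vector).
#' @param mesh the \code{labeled_tet_mesh} the state was computed on.
#' @param region region name (see [region_elements()]) or an explicit
#'   integer element id vector.
#' @param ... passed to [region_elements()].
#' @return one-row data frame: station, region, mean, min, max, sd (MPa).
#' @export
region_summary <- function(state, mesh, region, ...) {
  ids <- if (is.numeric(region)) as.integer(region)
  else region_elements(mesh, region, ...)
  vm <- state$vm[ids]
  w <- mesh$volumes[ids]
  m <- sum(w * vm) / sum(w)
  data.frame(station = if (!is.null(state$station)) state$station else NA_integer_,
             region = if (is.character(region)) region else "custom",
             mean = m, min = min(vm), max = max(vm),
             sd = sqrt(sum(w * (vm - m)^2) / sum(w)))
}

#' Regional stress table for a whole run
#'
#' The per-frame, per-region von Mises summary table (one row per frame and
#' region) for the three reported zones.
#'
#' @param fem a \code{delivery_fem} result.
#' @param regions region names.
#' @param side side passed to [region_elements()].
#' @return data frame with columns frame, station, region, mean, min, max,
#'   sd.
#' @export
summarize_run <- function(fem, regions = c("ICm", "pubic_attachment",
                                           "posteromedial_PRm"),
                          side = "left") {
  ids <- lapply(regions, region_elements, mesh = fem$mesh, side = side)
  out <- lapply(seq_along(fem$states), function(fi) {
    st <- fem$states[[fi]]
    rows <- lapply(seq_along(regions), function(k) {
      r <- region_summary(st, fem$mesh, ids[[k]])
      r$region <- regions[k]
      r
    })
    df <- do.call(rbind, rows)
    df$frame <- fi
    df
  })
  df <- do.call(rbind, out)
  df[, c("frame", "station", "region", "mean", "min", "max", "sd")]
}

#' @export
summary.delivery_fem <- function(object, ...) summarize_run(object, ...)

#' @export
plot.delivery_fem <- function(x, ...) {
  df <- summarize_run(x)
  regs <- unique(df$region)
  cols <- c("darkred", "steelblue", "darkorchid4")[seq_along(regs)]
  graphics::matplot(matrix(df$mean, ncol = length(regs), byrow = TRUE),
                    type = "l", lty = 1, col = cols,
                    xlab = "frame", ylab = "mean von Mises [MPa]",
                    main = "regional stress history", ...)
  graphics::legend("topleft", legend = regs, col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Order of regional stress engagement
#'
#' For each region, the first frame at which its volume-weighted mean von
#' Mises stress exceeds the engagement threshold (1 percent of that
#' region's own run-maximum mean by default: regional magnitudes differ by
#' orders of magnitude, so a single global threshold would never register
#' the weakly loaded regions); regions are returned in engagement order,
#' ties broken by region name.
#'
#' @param summaries a data frame from [summarize_run()].
#' @param threshold_frac engagement threshold as a fraction of the
#'   region's run-maximum mean.
#' @return data frame (region, first_frame, first_station) ordered by
#'   engagement; zero rows (with a warning) if nothing engages.
#' @export
loading_order <- function(summaries, threshold_frac = 0.01) {
  regs <- sort(unique(summaries$region))
  rows <- lapply(regs, function(r) {
    d <- summaries[summaries$region == r, ]
    d <- d[order(d$frame), ]
    thr <- threshold_frac * max(d$mean)
    i <- if (max(d$mean) > 0) which(d$mean > thr) else integer(0)
    if (length(i) == 0L) return(NULL)
    data.frame(region = r, first_frame = d$frame[i[1]],
               first_station = d$station[i[1]])
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    warning("no region ever exceeds the engagement threshold")
    return(data.frame(region = character(), first_frame = integer(),
                      first_station = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$first_frame, out$region), , drop = FALSE]
}

.polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

#' Mediosagittal elongation and caudal displacement report
#'
#' Tracks the ordered mediosagittal trace of the levator shell through the
#' run: per-frame arc length, the stretch ratio (deformed / initial arc
#' length, reported at the frame of maximal value), and the maximal caudal
#' (-z) displacement over the distal puborectal loop node set.
#'
#' @param states list of equilibrium states (or a \code{delivery_fem}).
#' @param mesh the \code{labeled_tet_mesh} (taken from the fit when a
#'   \code{delivery_fem} is given).
#' @return list: \code{initial_length_mm}, \code{length_mm} (per frame),
#'   \code{stretch_ratio} (per frame), \code{max_stretch_ratio},
#'   \code{frame_of_max}, \code{max_caudal_displacement_mm}.
#' @export
elongation_report <- function(states, mesh = NULL) {
  if (inherits(states, "delivery_fem")) {
    mesh <- states$mesh
    states <- states$states
  }
  tr <- mesh$mediosagittal_trace
  loop <- mesh$sets$distal_prm_loop
  if (is.null(tr) || is.null(loop))
    stop(errorCondition("mesh lacks mediosagittal_trace or distal_prm_loop sets",
                        class = c("levatorfem_lookup_error", "error", "condition")))
  L0 <- .polyline_length(mesh$nodes[tr, , drop = FALSE])
  lens <- vapply(states, function(s)
    .polyline_length(mesh$nodes[tr, , drop = FALSE] +
                       s$displacements[tr, , drop = FALSE]), numeric(1))
  caud <- vapply(states, function(s)
    max(c(0, -s$displacements[loop, 3])), numeric(1))
  ratio <- lens / L0
  list(initial_length_mm = L0, length_mm = lens, stretch_ratio = ratio,
       max_stretch_ratio = max(ratio), frame_of_max = which.max(ratio),
       max_caudal_displacement_mm = max(caud))
}

#' Write a regional stress table to CSV
#'
#' Table-layout export (head descent station by region with mean, min, max,
#' SD columns); reading the file back returns identical values.
#'
#' @param summaries data frame from [summarize_run()] (may be empty).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
export_table <- function(summaries, path) {
  cols <- c("frame", "station", "region", "mean", "min", "max", "sd")
  if (nrow(summaries) == 0L) {
    writeLines(paste(cols, collapse = ","), path)
    return(invisible(path))
  }
  ok <- tryCatch({
    utils::write.csv(summaries[, cols], path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok)
    stop(errorCondition(sprintf("cannot write table to '%s'", path),
                        class = c("levatorfem_io_error", "error", "condition")))
  invisible(path)
}
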