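#' Labeled nuclear mask
#'
#' Integer image in which 0 is background and k marks the pixels of nucleus
#' k; labels are contiguous 1..n_objects.
#'
#' @param labels integer matrix of labels.
#' @param connectivity how connected components were defined (recorded for
#'   provenance).
#' @return An object of class `"labeled_mask"`: list with `labels`, `shape`,
#'   `n_objects`, `connectivity`.
#' @export
labeled_mask <- function(labels, connectivity = "ebimage_bwlabel") {
  if (!is.matrix(labels)) abort("`labels` must be a matrix")
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  u <- sort(unique(labels[labels > 0]))
  if (length(u) && !identical(u, seq_along(u))) {
    # relabel contiguously, preserving order
    map <- integer(max(u)); map[u] <- seq_along(u)
    labels[labels > 0] <- map[labels[labels > 0]]
  }
  structure(list(labels = labels, shape = dim(labels),
                 n_objects = length(u), connectivity = connectivity),
            class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("<labeled_mask> %d x %d, %d object(s)\n",
              x$shape[1], x$shape[2], x$n_objects))
  invisible(x)
}

#' Segment nuclei by adaptive thresholding
#'
#' Local-mean adaptive threshold (via [EBImage::thresh()]) applied to a
#' nuclear-marker image, followed by connected-component labeling
#' ([EBImage::bwlabel()]), removal of objects below `min_area`, and
#' contiguous relabeling.
#'
#' @param nuclear_image 2-D numeric matrix of nuclear-marker intensities.
#' @param block_size side of the local averaging window in pixels (odd).
#' @param offset threshold offset above the local mean.
#' @param min_area minimum object area in pixels.
#' @return A [labeled_mask()].
#' @export
segment_nuclei <- function(nuclear_image, block_size = 51, offset = 0.01,
                           min_area = 40) {
  if (!is.matrix(nuclear_image) || !is.numeric(nuclear_image))
    abort("`nuclear_image` must be a 2-D numeric matrix")
  check_number(block_size, "block_size", lower = 3)
  check_number(min_area, "min_area", lower = 0)
  w <- max(1L, as.integer((block_size - 1) / 2))
  bw <- EBImage::thresh(EBImage::Image(nuclear_image), w = w, h = w,
                        offset = offset)
  lab <- EBImage::imageData(EBImage::bwlabel(bw))
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(areas < min_area)
    if (length(drop)) lab[lab %in% drop] <- 0
  }
  labeled_mask(lab)
}

shift_matrix <- function(m, dy, dx, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- max(1, 1 + dy):min(nr, nr + dy)
  xs <- max(1, 1 + dx):min(nc, nc + dx)
  if (length(ys) && length(xs))
    out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

#' Object-preserving label expansion (cytoplasmic ring construction)
#'
#' Dilates a labeled nuclear mask by assigning every background pixel within
#' Euclidean distance `radius` of some nucleus the label of its *nearest*
#' nucleus. Unlike a plain morphological dilation, touching objects never
#' merge: pixels between two nuclei go to the closer one (ties at equal
#' distance to the smaller label), so the number of objects is preserved and
#' original nuclear pixels are never reassigned.
#'
#' @param mask a [labeled_mask()].
#' @param radius expansion radius in pixels (default 5).
#' @return A [labeled_mask()] of the expanded labels.
#' @export
expand_labels_nearest <- function(mask, radius = 5) {
  if (!inherits(mask, "labeled_mask")) abort("`mask` must be a labeled_mask")
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0)
    abort("`radius` must be a single non-negative number")
  lab <- mask$labels
  if (radius == 0 || mask$n_objects == 0)
    return(labeled_mask(lab, mask$connectivity))
  r <- floor(radius)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs$d2 <- offs$dy^2 + offs$dx^2
  offs <- offs[offs$d2 > 0 & offs$d2 <= radius^2, ]
  out <- lab
  big <- .Machine$integer.max
  # scan offsets in shells of increasing distance; the first shell that
  # reaches a pixel is its nearest nucleus, and pmin over a shell breaks
  # equal-distance ties toward the smaller label
  for (d2 in sort(unique(offs$d2))) {
    shell <- offs[offs$d2 == d2, ]
    cand <- matrix(big, nrow(lab), ncol(lab))
    for (k in seq_len(nrow(shell))) {
      s <- shift_matrix(lab, shell$dy[k], shell$dx[k])
      s[s == 0L] <- big
      cand <- pmin(cand, s)
    }
    sel <- out == 0L & cand < big
    out[sel] <- cand[sel]
  }
  labeled_mask(out, mask$connectivity)
}

#' Measure per-cell log2 cytoplasm-to-nucleus ratios
#'
#' For each labeled nucleus, the mean reporter intensity over its nuclear
#' pixels and over its cytoplasmic ring (expanded label minus nucleus), and
#' `log2_cnr = log2(cytoplasm_mean / nuclear_mean)` — the standard KTR
#' activity readout. Being a ratio, the measurement is invariant to global
#' multiplicative intensity scaling. Cells with an empty ring or a
#' non-positive mean are dropped with a warning.
#'
#' @param nuclear_labels a [labeled_mask()] of nuclei.
#' @param expanded_labels the matching [expand_labels_nearest()] output.
#' @param reporter_image reporter-channel intensity matrix, same shape.
#' @return `data.frame` with columns `label`, `nuclear_mean`,
#'   `cytoplasm_mean`, `log2_cnr`, `x`, `y` (nuclear centroid).
#' @export
measure_cnr <- function(nuclear_labels, expanded_labels, reporter_image) {
  for (m in list(nuclear_labels, expanded_labels))
    if (!inherits(m, "labeled_mask")) abort("masks must be labeled_mask objects")
  if (!is.matrix(reporter_image) ||
      !identical(dim(reporter_image), nuclear_labels$shape))
    abort("`reporter_image` must match the mask shape")
  nuc <- nuclear_labels$labels
  ring <- expanded_labels$labels
  ring[nuc > 0] <- 0L  # cytoplasm = expanded minus nuclear, disjoint by construction
  n <- nuclear_labels$n_objects
  if (n == 0L)
    return(data.frame(label = integer(0), nuclear_mean = numeric(0),
                      cytoplasm_mean = numeric(0), log2_cnr = numeric(0),
                      x = numeric(0), y = numeric(0)))
  mean_by <- function(lab) {
    s <- rep(NA_real_, n)
    sel <- lab > 0
    if (any(sel)) {
      agg <- tapply(reporter_image[sel], lab[sel], mean)
      s[as.integer(names(agg))] <- agg
    }
    s
  }
  nm <- mean_by(nuc); cm <- mean_by(ring)
  idx <- which(nuc > 0)
  rows <- ((idx - 1) %% nrow(nuc)) + 1
  cols <- ((idx - 1) %/% nrow(nuc)) + 1
  cx <- tapply(rows, nuc[idx], mean)
  cy <- tapply(cols, nuc[idx], mean)
  x <- rep(NA_real_, n); y <- rep(NA_real_, n)
  x[as.integer(names(cx))] <- cx
  y[as.integer(names(cy))] <- cy
  ok <- !is.na(cm) & !is.na(nm) & cm > 0 & nm > 0
  if (any(!ok))
    warning(sum(!ok),
            " object(s) dropped (empty cytoplasm ring or non-positive mean)")
  data.frame(label = which(ok), nuclear_mean = nm[ok], cytoplasm_mean = cm[ok],
             log2_cnr = log2(cm[ok] / nm[ok]), x = x[ok], y = y[ok])
}

#' Link nuclei across frames by maximal pixel overlap
#'
#' Greedy overlap tracking: for each pair of successive frames, candidate
#' links are ranked by the number of shared pixels and accepted in descending
#' order, skipping any source or target already used (so the frame-pair
#' mapping is injective — nuclei never merge into one track). Ties go to the
#' smaller source, then target, label. A nucleus with zero overlap in the
#' next frame ends its track; unmatched nuclei start new tracks.
#'
#' @param mask_sequence list of [labeled_mask()] objects (>= 2 frames, equal
#'   shape).
#' @return An object of class `"track_graph"`: list with `links` (per
#'   frame-pair `data.frame` of `from`, `to`, `overlap`), `tracks`
#'   (`data.frame` of `track_id`, `frame`, `label`), `n_frames`, and
#'   `complete` (named logical: tracks spanning every frame).
#' @export
link_tracks <- function(mask_sequence) {
  if (!is.list(mask_sequence) || length(mask_sequence) < 2L)
    abort("tracking needs at least 2 frames")
  shapes <- lapply(mask_sequence, function(m) {
    if (!inherits(m, "labeled_mask")) abort("frames must be labeled_mask objects")
    m$shape
  })
  if (!all(vapply(shapes, identical, logical(1), shapes[[1]])))
    abort("all frames must share the same shape")
  n_frames <- length(mask_sequence)
  links <- vector("list", n_frames - 1L)
  for (t in seq_len(n_frames - 1L)) {
    a <- mask_sequence[[t]]$labels
    b <- mask_sequence[[t + 1L]]$labels
    sel <- a > 0 & b > 0
    if (!any(sel)) {
      links[[t]] <- data.frame(from = integer(0), to = integer(0),
                               overlap = integer(0))
      next
    }
    tab <- as.data.frame(table(from = a[sel], to = b[sel]),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0, ]
    tab$from <- as.integer(tab$from); tab$to <- as.integer(tab$to)
    tab <- tab[order(-tab$Freq, tab$from, tab$to), ]
    used_from <- logical(mask_sequence[[t]]$n_objects)
    used_to <- logical(mask_sequence[[t + 1L]]$n_objects)
    keep <- logical(nrow(tab))
    for (i in seq_len(nrow(tab))) {
      if (!used_from[tab$from[i]] && !used_to[tab$to[i]]) {
        keep[i] <- TRUE
        used_from[tab$from[i]] <- TRUE
        used_to[tab$to[i]] <- TRUE
      }
    }
    links[[t]] <- data.frame(from = tab$from[keep], to = tab$to[keep],
                             overlap = tab$Freq[keep])
  }
  # assemble maximal chains
  next_id <- 0L
  active <- integer(0)  # track id per label of current frame
  rows <- list()
  for (t in seq_len(n_frames)) {
    n_obj <- mask_sequence[[t]]$n_objects
    ids <- rep(NA_integer_, n_obj)
    if (t > 1L) {
      lk <- links[[t - 1L]]
      ids[lk$to] <- active[lk$from]
    }
    for (j in seq_len(n_obj)) {
      if (is.na(ids[j])) {
        next_id <- next_id + 1L
        ids[j] <- next_id
      }
      rows[[length(rows) + 1L]] <-
        data.frame(track_id = ids[j], frame = t, label = j)
    }
    active <- ids
  }
  tracks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(0), frame = integer(0), label = integer(0))
  span <- tapply(tracks$frame, tracks$track_id, length)
  complete <- setNames(as.vector(span) == n_frames, names(span))
  structure(list(links = links, tracks = tracks, n_frames = n_frames,
                 complete = complete), class = "track_graph")
}

#' @export
print.track_graph <- function(x, ...) {
  cat(sprintf("<track_graph> %d frames, %d track(s), %d complete\n",
              x$n_frames, length(x$complete), sum(x$complete)))
  invisible(x)
}

#' Process a two-channel time-lapse stack into single-cell trajectories
#'
#' The full automated image-processing pipeline: per frame, segment nuclei
#' ([segment_nuclei()]), build cytoplasmic rings ([expand_labels_nearest()])
#' and measure per-cell log2(CNR) in every reporter channel
#' ([measure_cnr()]); then link nuclei across frames by maximal overlap
#' ([link_tracks()]) and emit one trajectory per tracked cell per channel.
#'
#' @param nuclear_stack 3-D array (rows x cols x frames) of nuclear-marker
#'   images.
#' @param reporter_stacks named list of 3-D arrays, one per reporter channel
#'   (e.g. `list(Akt = ..., ERK = ...)`), aligned with `nuclear_stack`.
#' @param acquisition_times frame times in minutes (length = n frames).
#' @param block_size,offset,min_area passed to [segment_nuclei()].
#' @param radius ring expansion radius, passed to [expand_labels_nearest()].
#' @return List with `trajectories` (long `data.frame`: `cell_id`, `channel`,
#'   `time_min`, `log2_cnr`, `complete`), `tracks` (the [link_tracks()]
#'   graph) and `masks` (per-frame [labeled_mask()]s).
#' @export
process_stack <- function(nuclear_stack, reporter_stacks, acquisition_times,
                          block_size = 51, offset = 0.01, min_area = 40,
                          radius = 5) {
  if (length(dim(nuclear_stack)) != 3L)
    abort("`nuclear_stack` must be a rows x cols x frames array")
  n_frames <- dim(nuclear_stack)[3]
  if (n_frames < 2L) abort("tracking needs at least 2 frames")
  if (!is.list(reporter_stacks) || is.null(names(reporter_stacks)) ||
      any(!nzchar(names(reporter_stacks))))
    abort("`reporter_stacks` must be a named list of arrays")
  for (ch in names(reporter_stacks))
    if (!identical(dim(reporter_stacks[[ch]]), dim(nuclear_stack)))
      abort(sprintf("reporter stack '%s' does not match the nuclear stack", ch))
  if (length(acquisition_times) != n_frames)
    abort("`acquisition_times` must have one entry per frame")

  masks <- vector("list", n_frames)
  meas <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    m <- tryCatch(
      segment_nuclei(nuclear_stack[, , t], block_size, offset, min_area),
      error = function(e)
        abort(sprintf("segmentation failed at frame %d: %s", t,
                      conditionMessage(e))))
    masks[[t]] <- m
    exp_m <- expand_labels_nearest(m, radius)
    meas[[t]] <- lapply(reporter_stacks, function(stk)
      suppressWarnings(measure_cnr(m, exp_m, stk[, , t])))
  }
  graph <- link_tracks(masks)
  tr <- graph$tracks
  rows <- list()
  for (id in unique(tr$track_id)) {
    seg <- tr[tr$track_id == id, ]
    cid <- sprintf("cell_%04d", id)
    for (ch in names(reporter_stacks)) {
      vals <- numeric(0); tms <- numeric(0)
      for (i in seq_len(nrow(seg))) {
        mm <- meas[[seg$frame[i]]][[ch]]
        j <- match(seg$label[i], mm$label)
        if (!is.na(j)) {
          vals <- c(vals, mm$log2_cnr[j])
          tms <- c(tms, acquisition_times[seg$frame[i]])
        }
      }
      if (length(vals))
        rows[[length(rows) + 1L]] <- data.frame(
          cell_id = cid, channel = ch, time_min = tms, log2_cnr = vals,
          complete = unname(graph$complete[as.character(id)]) &&
            length(vals) == n_frames)
    }
  }
  trajectories <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(0), channel = character(0),
               time_min = numeric(0), log2_cnr = numeric(0),
               complete = logical(0))
  rownames(trajectories) <- NULL
  list(trajectories = trajectories, tracks = graph, masks = masks)
}
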