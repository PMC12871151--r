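# Augmented-matrix linear assignment between two point sets: candidate links
# cost = squared displacement, capped by per-pair allowed radius; unmatched
# points pay the alternative cost alt_cost. Returns integer match vector
# (index into set b, NA = unmatched) for set a.
lap_match <- function(ax, ay, bx, by, max_r, alt_cost) {
  n1 <- length(ax); n2 <- length(bx)
  if (n1 == 0 || n2 == 0) return(rep(NA_integer_, n1))
  d2 <- outer(ax, bx, "-")^2 + outer(ay, by, "-")^2
  if (is.matrix(max_r)) allowed <- d2 <= max_r^2 else allowed <- d2 <= max_r^2
  big <- (max(d2[allowed], alt_cost, 1) + 1) * 1e6
  C <- matrix(big, n1 + n2, n1 + n2)
  cb <- d2; cb[!allowed] <- big
  C[1:n1, 1:n2] <- cb
  C[cbind(1:n1, n2 + 1:n1)] <- alt_cost            # death
  C[cbind(n1 + 1:n2, 1:n2)] <- alt_cost            # birth
  C[n1 + 1:n2, n2 + 1:n1] <- 0                     # dummy-dummy
  sol <- as.integer(clue::solve_LSAP(C))
  m <- sol[1:n1]
  m[m > n2] <- NA_integer_
  # refuse links that fell back on the big penalty (no feasible partner)
  bad <- !is.na(m) & !allowed[cbind(seq_len(n1), ifelse(is.na(m), 1L, m))]
  m[bad] <- NA_integer_
  m
}

#' Link per-frame detections into adhesion trajectories
#'
#' Frame-to-frame globally optimal assignment (Hungarian algorithm on
#' squared displacement, alternative cost = `search_radius^2` for track
#' birth/death) followed by gap closing: a track end may be joined to a
#' track start up to `max_gap` missing frames later, within a search radius
#' scaled by the gap length. Every detection ends up in exactly one track;
#' isolated detections become singleton tracks, so the sum of track lengths
#' equals the number of detections.
#'
#' @param detections data frame with columns `frame` (0-based), `x`, `y` and
#'   any others (carried through), sorted by frame.
#' @param search_radius maximum frame-to-frame displacement in pixels.
#' @param max_gap maximum number of consecutive missing frames bridged by
#'   gap closing (0 disables it).
#' @return The input data frame with a `track_id` column (1-based, dense),
#'   ordered by track then frame.
#' @export
link_detections <- function(detections, search_radius = 3, max_gap = 2) {
  if (search_radius < 0 || max_gap < 0)
    stop("search_radius and max_gap must be non-negative")
  stopifnot(is.data.frame(detections),
            all(c("frame", "x", "y") %in% names(detections)))
  det <- detections[order(detections$frame), , drop = FALSE]
  n <- nrow(det)
  if (n == 0) { det$track_id <- integer(0); return(det) }

  frames <- sort(unique(det$frame))
  idx_by_frame <- split(seq_len(n), det$frame)
  track_of <- integer(n)
  track_of[idx_by_frame[[1]]] <- seq_along(idx_by_frame[[1]])
  n_tracks <- length(idx_by_frame[[1]])

  for (k in seq_len(length(frames) - 1)) {
    ia <- idx_by_frame[[k]]
    ib <- idx_by_frame[[k + 1]]
    if (frames[k + 1] - frames[k] == 1) {
      m <- lap_match(det$x[ia], det$y[ia], det$x[ib], det$y[ib],
                     max_r = search_radius, alt_cost = search_radius^2)
    } else {
      m <- rep(NA_integer_, length(ia))
    }
    linked_b <- rep(FALSE, length(ib))
    for (j in seq_along(ia)) {
      if (!is.na(m[j])) {
        track_of[ib[m[j]]] <- track_of[ia[j]]
        linked_b[m[j]] <- TRUE
      }
    }
    for (j in which(!linked_b)) {
      n_tracks <- n_tracks + 1L
      track_of[ib[j]] <- n_tracks
    }
  }

  # gap closing on segment ends/starts
  if (max_gap > 0 && n_tracks > 1) {
    first_i <- tapply(seq_len(n), track_of, function(i) i[which.min(det$frame[i])])
    last_i <- tapply(seq_len(n), track_of, function(i) i[which.max(det$frame[i])])
    ends <- data.frame(tr = as.integer(names(last_i)),
                       frame = det$frame[last_i],
                       x = det$x[last_i], y = det$y[last_i])
    starts <- data.frame(tr = as.integer(names(first_i)),
                         frame = det$frame[first_i],
                         x = det$x[first_i], y = det$y[first_i])
    dt <- outer(starts$frame, ends$frame, "-")   # start - end, rows = starts
    d2 <- outer(starts$x, ends$x, "-")^2 + outer(starts$y, ends$y, "-")^2
    rmax <- search_radius * dt
    feasible <- dt >= 2 & dt <= max_gap + 1 & d2 <= rmax^2 &
      outer(starts$tr, ends$tr, "!=")
    if (any(feasible)) {
      alt <- (search_radius * (max_gap + 1))^2
      big <- (max(d2) + alt + 1) * 1e6
      C <- d2; C[!feasible] <- big
      ns <- nrow(starts); ne <- nrow(ends)
      M <- matrix(big, ns + ne, ns + ne)
      M[1:ns, 1:ne] <- C
      M[cbind(1:ns, ne + 1:ns)] <- alt
      M[cbind(ns + 1:ne, 1:ne)] <- alt
      M[ns + 1:ne, ne + 1:ns] <- 0
      sol <- as.integer(clue::solve_LSAP(M))
      # union-find style relabel: start segment inherits end segment's track
      parent <- seq_len(n_tracks)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (j in seq_len(ns)) {
        e <- sol[j]
        if (e <= ne && feasible[j, e])
          parent[find(starts$tr[j])] <- find(ends$tr[e])
      }
      track_of <- vapply(track_of, find, integer(1))
    }
  }

  det$track_id <- match(track_of, unique(track_of))
  det[order(det$track_id, det$frame), , drop = FALSE]
}

#' Assign per-frame maturation status to tracked adhesions
#'
#' Each tracked point is compared with the frame's FC/FA segmentation:
#' a position inside an FA-class region gets status `"FA"`, inside an
#' FC-class region `"FC"`, and a detection outside both (including inside a
#' sub-FC region) is a nascent adhesion, `"NA"`. When `back_extend > 0`,
#' that many frames before the first detection (bounded at frame 0) are
#' prepended with status `"BA"` (before adhesion); such rows carry the first
#' detection's position and `NA` amplitude.
#'
#' @param tracks data frame from [link_detections()].
#' @param segmentations per-frame list from [segment_stack()]; must cover
#'   every frame index present in `tracks`.
#' @param back_extend number of BA frames to prepend per track.
#' @return `tracks` with a `status` column (and BA rows if requested),
#'   ordered by track then frame.
#' @export
assign_status <- function(tracks, segmentations, back_extend = 0) {
  stopifnot(is.data.frame(tracks), is.list(segmentations))
  if (nrow(tracks) == 0) { tracks$status <- character(0); return(tracks) }
  if (max(tracks$frame) + 1 > length(segmentations))
    stop("segmentations do not cover all track frames")
  status <- character(nrow(tracks))
  for (i in seq_len(nrow(tracks))) {
    f <- tracks$frame[i] + 1
    seg <- segmentations[[f]]
    r <- round(tracks$y[i]) + 1; c <- round(tracks$x[i]) + 1
    lab <- 0L
    if (r >= 1 && r <= nrow(seg$labels) && c >= 1 && c <= ncol(seg$labels))
      lab <- seg$labels[r, c]
    if (lab > 0) {
      cls <- seg$regions$adhesion_class[seg$regions$label == lab]
      status[i] <- if (cls %in% c("FA", "FC")) cls else "NA"
    } else status[i] <- "NA"
  }
  tracks$status <- status
  if (back_extend > 0) {
    ba <- lapply(split(tracks, tracks$track_id), function(tr) {
      f0 <- min(tr$frame)
      fb <- seq(max(0, f0 - back_extend), f0 - 1)
      if (length(fb) == 0 || f0 == 0) return(NULL)
      out <- tr[rep(which.min(tr$frame), length(fb)), , drop = FALSE]
      out$frame <- fb
      out$amplitude <- NA_real_
      out$status <- "BA"
      out
    })
    tracks <- rbind(tracks, do.call(rbind, ba))
  }
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  tracks
}

# per-track summary used by lifetime / nucleation statistics
track_summary <- function(tracks) {
  sp <- split(tracks, tracks$track_id)
  do.call(rbind, lapply(sp, function(tr) {
    det <- tr[tr$status != "BA", , drop = FALSE]
    data.frame(
      track_id = tr$track_id[1],
      first_frame = min(det$frame), last_frame = max(det$frame),
      n_frames = max(det$frame) - min(det$frame) + 1,
      matured = any(det$status %in% c("FC", "FA")),
      born_na = det$status[which.min(det$frame)] == "NA")
  }))
}

#' Adhesion lifetimes from tracked trajectories
#'
#' Lifetime convention: (number of frames spanned by the track, gap-closed
#' frames included) times the frame interval. Nascent-adhesion lifetimes
#' come from tracks that never overlap an FC/FA segmentation; FC/FA
#' lifetimes from tracks that contain FC or FA status at any time. Tracks
#' alive at the first or last movie frame are censored and excluded from
#' the default lists.
#'
#' @param tracks data frame with `status` from [assign_status()].
#' @param frame_interval seconds between frames.
#' @param n_movie_frames total frames in the movie (for right-censoring).
#' @param include_censored keep censored tracks in the lifetime lists.
#' @return List with `na_lifetimes`, `fa_lifetimes` (seconds) and `tracks`,
#'   the per-track table with `lifetime`, `left_censored`, `right_censored`.
#' @export
compute_lifetimes <- function(tracks, frame_interval, n_movie_frames,
                              include_censored = FALSE) {
  ts <- track_summary(tracks)
  ts$lifetime <- ts$n_frames * frame_interval
  ts$left_censored <- ts$first_frame == 0
  ts$right_censored <- ts$last_frame == n_movie_frames - 1
  use <- if (include_censored) rep(TRUE, nrow(ts)) else
    !(ts$left_censored | ts$right_censored)
  list(
    na_lifetimes = ts$lifetime[use & !ts$matured],
    fa_lifetimes = ts$lifetime[use & ts$matured],
    tracks = ts)
}

#' Nucleation and maturation fractions of a tracked movie
#'
#' A nucleating nascent adhesion is a track whose first detection occurs
#' after the first movie frame and which persists at least `min_frames`
#' frames. The nucleating fraction is taken over all NA-containing tracks;
#' the maturing fraction is the share of NA-born tracks that ever reach FC
#' or FA status.
#'
#' @param tracks data frame with `status` from [assign_status()].
#' @param min_frames persistence requirement for a nucleation event.
#' @return List with `nucleating_fraction`, `maturing_fraction` (either is
#'   `NA` with a `reason` attribute when its denominator is zero) and the
#'   underlying counts.
#' @export
nucleation_and_maturation <- function(tracks, min_frames = 3) {
  ts <- track_summary(tracks)
  has_na <- vapply(split(tracks, tracks$track_id),
                   function(tr) any(tr$status == "NA"), logical(1))
  ts$has_na <- has_na[as.character(ts$track_id)]
  nucleated <- ts$first_frame > 0 & ts$n_frames >= min_frames & ts$has_na
  denom_nuc <- sum(ts$has_na)
  denom_mat <- sum(ts$born_na)
  nf <- if (denom_nuc > 0) sum(nucleated) / denom_nuc else
    structure(NA_real_, reason = "no NA-containing tracks")
  mf <- if (denom_mat > 0) sum(ts$matured & ts$born_na) / denom_mat else
    structure(NA_real_, reason = "no NA-born tracks")
  list(nucleating_fraction = nf, maturing_fraction = mf,
       n_nucleating = sum(nucleated), n_na_tracks = denom_nuc,
       n_matured = sum(ts$matured & ts$born_na), n_na_born = denom_mat)
}
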