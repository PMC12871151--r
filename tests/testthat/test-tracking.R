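test_that("two close detections in consecutive frames form one track", {
  det <- data.frame(frame = 0:1, x = c(10, 11), y = c(10, 10),
                    amplitude = 1)
  tr <- link_detections(det, search_radius = 5, max_gap = 0)
  expect_equal(length(unique(tr$track_id)), 1)
})

test_that("detections beyond the search radius stay separate", {
  det <- data.frame(frame = 0:1, x = c(10, 20), y = c(10, 10),
                    amplitude = 1)
  tr <- link_detections(det, search_radius = 3, max_gap = 0)
  expect_equal(length(unique(tr$track_id)), 2)
  expect_error(link_detections(det, search_radius = -1), "non-negative")
})

test_that("parallel movers keep their identities over 20 frames", {
  det <- do.call(rbind, lapply(0:19, function(f)
    data.frame(frame = f, x = c(10 + 0.8 * f, 20 + 0.8 * f), y = c(10, 10),
               amplitude = 1, truth_id = c(1, 2))))
  tr <- link_detections(det, search_radius = 3, max_gap = 2)
  expect_equal(length(unique(tr$track_id)), 2)
  # no identity swaps: each track carries exactly one truth id
  swaps <- tapply(tr$truth_id, tr$track_id, function(v)
    length(unique(v)))
  expect_true(all(swaps == 1))
})

test_that("planted random walks are linked with >= 98% correct links", {
  set.seed(42)
  n_spots <- 30; n_frames <- 20
  pos <- planted_spot_positions(n_spots, 300, 300, margin = 15,
                                min_sep = 18)
  det <- list()
  for (f in 0:(n_frames - 1)) {
    det[[f + 1]] <- data.frame(frame = f, x = pos$x, y = pos$y,
                               amplitude = 1, truth_id = seq_len(n_spots))
    pos$x <- pos$x + runif(n_spots, -1.4, 1.4)   # <= 2 px/frame
    pos$y <- pos$y + runif(n_spots, -1.4, 1.4)
  }
  det <- do.call(rbind, det)
  tr <- link_detections(det, search_radius = 4, max_gap = 2)
  tr <- tr[order(tr$track_id, tr$frame), ]
  links <- do.call(rbind, lapply(split(tr, tr$track_id), function(g)
    if (nrow(g) > 1) data.frame(a = g$truth_id[-nrow(g)],
                                b = g$truth_id[-1]) else NULL))
  expect_gte(mean(links$a == links$b), 0.98)
  # conservation: every detection in exactly one track
  expect_equal(nrow(tr), nrow(det))
  expect_equal(sum(table(tr$track_id)), nrow(det))
})

test_that("gap closing bridges a missing frame", {
  det <- data.frame(frame = c(0, 1, 3, 4), x = c(10, 10.5, 11.5, 12),
                    y = 10, amplitude = 1)
  tr <- link_detections(det, search_radius = 3, max_gap = 2)
  expect_equal(length(unique(tr$track_id)), 1)
  tr0 <- link_detections(det, search_radius = 3, max_gap = 0)
  expect_equal(length(unique(tr0$track_id)), 2)
})

test_that("status assignment follows segmentation overlap", {
  lab <- matrix(0L, 50, 50)
  lab[10:20, 10:30] <- 1L            # FA-class region
  lab[35:38, 35:38] <- 2L            # FC-class region
  seg <- list(regions = data.frame(
    label = 1:2, area = c(2, 0.4), major_axis = 1, minor_axis = 1,
    eccentricity_ratio = 1, adhesion_class = c("FA", "FC"),
    centroid_x = 0, centroid_y = 0), labels = lab)
  tracks <- data.frame(track_id = c(1, 2, 3), frame = 0,
                       x = c(20, 36, 45), y = c(15, 36, 45),
                       amplitude = 1)
  out <- assign_status(tracks, list(seg))
  expect_equal(out$status[order(out$track_id)], c("FA", "FC", "NA"))
  expect_error(assign_status(transform(tracks, frame = 5), list(seg)),
               "cover")
})

test_that("status flips NA to FC when a growing region reaches the track", {
  segs <- lapply(0:14, function(f) {
    lab <- matrix(0L, 40, 40)
    cls <- "FC"
    if (f >= 10) lab[18:22, 18:22] <- 1L      # region appears at frame 10
    list(regions = data.frame(label = 1L, area = 0.4, major_axis = 1,
                              minor_axis = 1, eccentricity_ratio = 1,
                              adhesion_class = cls, centroid_x = 20,
                              centroid_y = 20)[(f >= 10), , drop = FALSE],
         labels = lab)
  })
  tracks <- data.frame(track_id = 1, frame = 0:14, x = 20, y = 20,
                       amplitude = 1)
  out <- assign_status(tracks, segs)
  expect_equal(out$status, c(rep("NA", 10), rep("FC", 5)))
})

test_that("BA back-extension precedes detection and never follows it", {
  lab <- matrix(0L, 30, 30)
  seg <- list(regions = data.frame(label = integer(0),
                                   adhesion_class = character(0)),
              labels = lab)
  tracks <- data.frame(track_id = 1, frame = 3:6, x = 10, y = 10,
                       amplitude = 1)
  out <- assign_status(tracks, rep(list(seg), 8), back_extend = 2)
  expect_equal(out$status, c("BA", "BA", "NA", "NA", "NA", "NA"))
  ba_idx <- which(out$status == "BA")
  expect_true(all(ba_idx < min(which(out$status != "BA"))))
})

test_that("lifetimes follow the frames-spanned convention with censoring", {
  mk <- function(id, frames) data.frame(track_id = id, frame = frames,
                                        x = 1, y = 1, amplitude = 1,
                                        status = "NA")
  tracks <- rbind(mk(1, 5:14), mk(2, 0:4), mk(3, 15:19))
  lt <- compute_lifetimes(tracks, frame_interval = 20,
                          n_movie_frames = 20)
  expect_equal(lt$na_lifetimes, 200)            # 10 frames x 20 s
  expect_true(lt$tracks$left_censored[lt$tracks$track_id == 2])
  expect_true(lt$tracks$right_censored[lt$tracks$track_id == 3])
  expect_equal(length(lt$na_lifetimes), 1)
})

test_that("uncensored lifetime mean recovers planted exponential survival", {
  set.seed(77)
  dt <- 20; n_frames <- 400
  n <- 200
  births <- sample(1:100, n, replace = TRUE)
  lives <- pmax(1, round(rexp(n, rate = dt / 300) ))  # mean 300 s / dt
  tracks <- do.call(rbind, lapply(seq_len(n), function(i) {
    fr <- births[i]:min(births[i] + lives[i] - 1, n_frames - 1)
    data.frame(track_id = i, frame = fr, x = 1, y = 1, amplitude = 1,
               status = "NA")
  }))
  lt <- compute_lifetimes(tracks, dt, n_frames)
  expect_equal(mean(lt$na_lifetimes), mean(lives[births + lives - 1 <
                                                   n_frames] * dt),
               tolerance = 1e-9)
  expect_equal(mean(lt$na_lifetimes), 300, tolerance = 0.15)
})

test_that("nucleation and maturation fractions count as defined", {
  mk <- function(id, frames, status) data.frame(
    track_id = id, frame = frames, x = 1, y = 1, amplitude = 1,
    status = status)
  # 10 tracks: 4 born after frame 0 and persistent, 6 present at frame 0
  tracks <- do.call(rbind, c(
    lapply(1:4, function(i) mk(i, 5:10, "NA")),
    lapply(5:10, function(i) mk(i, 0:5, "NA"))))
  nm <- nucleation_and_maturation(tracks)
  expect_equal(nm$nucleating_fraction, 0.4)
  # all present at frame 0 -> 0
  nm0 <- nucleation_and_maturation(do.call(rbind, lapply(1:5, function(i)
    mk(i, 0:5, "NA"))))
  expect_equal(nm0$nucleating_fraction, 0)
  # maturation: 2 of 4 NA-born tracks reach FC
  tracks2 <- rbind(mk(1, 1:6, c(rep("NA", 3), rep("FC", 3))),
                   mk(2, 1:6, c(rep("NA", 3), rep("FA", 3))),
                   mk(3, 1:6, "NA"), mk(4, 1:6, "NA"))
  expect_equal(nucleation_and_maturation(tracks2)$maturing_fraction, 0.5)
})

test_that("planted 30% maturation is recovered within the binomial CI", {
  set.seed(88)
  n <- 100
  mature <- rbinom(n, 1, 0.3) == 1
  tracks <- do.call(rbind, lapply(seq_len(n), function(i) {
    st <- if (mature[i]) c(rep("NA", 4), rep("FC", 4)) else rep("NA", 8)
    data.frame(track_id = i, frame = 2:9, x = 1, y = 1, amplitude = 1,
               status = st)
  }))
  mf <- nucleation_and_maturation(tracks)$maturing_fraction
  ci <- qbinom(c(0.025, 0.975), n, 0.3) / n
  expect_gte(mf, ci[1]); expect_lte(mf, ci[2])
})

test_that("concatenating movies shifts lifetimes by the time offset", {
  mk <- function(id, frames) data.frame(track_id = id, frame = frames,
                                        x = 1, y = 1, amplitude = 1,
                                        status = "NA")
  t1 <- mk(1, 5:9)
  lt1 <- compute_lifetimes(t1, 20, 30)
  t2 <- mk(1, 35:39)                       # same track, second movie
  lt2 <- compute_lifetimes(t2, 20, 60)
  expect_equal(lt1$na_lifetimes, lt2$na_lifetimes)
})
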