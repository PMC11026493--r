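blank_field <- function(nr = 96, nc = 96, bg = 0.1) matrix(bg, nr, nc)

disks_image <- function(centers, r = 7, nr = 96, nc = 96, bg = 0.1,
                        fg = 0.9) {
  img <- blank_field(nr, nc, bg)
  for (i in seq_len(nrow(centers)))
    img <- draw_disk(img, centers[i, 1], centers[i, 2], r, fg)
  img
}

disks_mask <- function(centers, r = 7, nr = 96, nc = 96) {
  m <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(centers)))
    m <- draw_disk(m, centers[i, 1], centers[i, 2], r, i)
  labeled_mask(m)
}

test_that("adaptive segmentation finds well-separated nuclei", {
  expect_equal(segment_nuclei(blank_field())$n_objects, 0L)
  centers <- rbind(c(25, 25), c(25, 70), c(70, 30), c(72, 72))
  seg <- segment_nuclei(disks_image(centers))
  expect_equal(seg$n_objects, 4L)
  # per-nucleus intersection over union against the drawn ground truth
  truth <- disks_mask(centers)
  for (k in 1:4) {
    gt <- truth$labels == k
    best <- max(vapply(seq_len(seg$n_objects), function(j) {
      got <- seg$labels == j
      sum(gt & got) / sum(gt | got)
    }, numeric(1)))
    expect_gt(best, 0.7)
  }
  expect_error(segment_nuclei(array(0, c(4, 4, 2))),
               class = "scdose_invalid_input")
})

test_that("label expansion preserves objects and assigns nearest labels", {
  one <- disks_mask(rbind(c(48, 48)), r = 7)
  ex <- expand_labels_nearest(one, 5)
  expect_equal(ex$n_objects, 1L)
  # the ring extends exactly 5 px beyond the disk along the axes
  expect_equal(ex$labels[48, 60], 1L)
  expect_equal(ex$labels[48, 61], 0L)
  expect_identical(ex$labels, brute_expand(one, 5)$labels)
  # no original nuclear pixel is ever reassigned
  expect_true(all(ex$labels[one$labels > 0] == one$labels[one$labels > 0]))
  # two nuclei 6 px apart (edge to edge): both survive, midline split by distance
  two <- disks_mask(rbind(c(48, 30), c(48, 50)), r = 7)
  ex2 <- expand_labels_nearest(two, 5)
  expect_equal(ex2$n_objects, 2L)
  mid_col <- 40 # equidistant from both nuclear boundaries
  expect_true(all(ex2$labels[, seq_len(mid_col - 1)] %in% c(0L, 1L)))
  expect_true(all(ex2$labels[, seq(mid_col + 1, 96)] %in% c(0L, 2L)))
  expect_error(expand_labels_nearest(two, -1), class = "scdose_invalid_input")
})

test_that("label expansion matches the brute-force nearest-seed search", {
  set.seed(17)
  for (rep in 1:5) {
    m <- matrix(0L, 64, 64)
    n_seed <- sample(2:5, 1)
    for (k in seq_len(n_seed)) {
      cy <- sample(8:56, 1); cx <- sample(8:56, 1)
      m <- draw_disk(m, cy, cx, sample(2:5, 1), k)
    }
    mask <- labeled_mask(m)
    expect_identical(expand_labels_nearest(mask, 5)$labels,
                     brute_expand(mask, 5)$labels)
  }
})

test_that("CNR measurement is exact on constructed intensities and scale-free", {
  centers <- rbind(c(30, 30), c(30, 70), c(70, 50))
  nuc <- disks_mask(centers, r = 6)
  ex <- expand_labels_nearest(nuc, 5)
  # uniform reporter: ratio 1 everywhere
  m0 <- measure_cnr(nuc, ex, blank_field(bg = 0.5))
  expect_equal(m0$log2_cnr, rep(0, 3))
  # cytoplasm exactly twice nuclear
  rep_img <- blank_field(bg = 0.4)
  rep_img[nuc$labels > 0] <- 0.2
  m1 <- measure_cnr(nuc, ex, rep_img)
  expect_equal(m1$log2_cnr, rep(1, 3))
  # invariant to global multiplicative scaling
  m2 <- measure_cnr(nuc, ex, 7.3 * rep_img)
  expect_equal(m2$log2_cnr, m1$log2_cnr)
  # nuclear and ring pixel sets are disjoint
  ring <- ex$labels
  ring[nuc$labels > 0] <- 0L
  expect_equal(sum(ring > 0 & nuc$labels > 0), 0L)
  # an empty ring drops the measurement with a warning
  expect_warning(m3 <- measure_cnr(nuc, nuc, rep_img), "dropped")
  expect_equal(nrow(m3), 0L)
})

test_that("overlap tracking links drifting nuclei and ends lost tracks", {
  centers <- rbind(c(20, 20), c(20, 60), c(60, 40))
  static <- replicate(10, disks_mask(centers), simplify = FALSE)
  g <- link_tracks(static)
  expect_equal(length(g$complete), 3L)
  expect_true(all(g$complete))
  expect_true(all(g$tracks$label == g$tracks$track_id))
  # 2 px/frame drift with ~15 px nuclei: all links correct
  drift <- lapply(0:9, function(t)
    disks_mask(centers + 2 * t, r = 7))
  gd <- link_tracks(drift)
  expect_equal(sum(gd$complete), 3L)
  for (lk in gd$links) expect_equal(lk$from, lk$to)
  # injectivity of every frame-pair mapping
  for (lk in gd$links) {
    expect_equal(anyDuplicated(lk$from), 0L)
    expect_equal(anyDuplicated(lk$to), 0L)
  }
  # a nucleus disappearing at frame 6 leaves a 5-frame track
  vanish <- c(replicate(5, disks_mask(centers), simplify = FALSE),
              replicate(5, disks_mask(centers[1:2, ]), simplify = FALSE))
  gv <- link_tracks(vanish)
  lens <- tapply(gv$tracks$frame, gv$tracks$track_id, length)
  expect_setequal(as.vector(lens), c(10, 10, 5))
  expect_error(link_tracks(static[1]), class = "scdose_invalid_input")
})

test_that("greedy linking picks the maximal-overlap assignment", {
  # two nuclei swap proximity: the larger overlap must win
  a <- disks_mask(rbind(c(30, 30), c(30, 52)), r = 7)
  # second frame: nucleus 1 sits between the two, overlapping both previous
  # nuclei; nucleus 2 overlaps nucleus 2 most
  b <- disks_mask(rbind(c(30, 40), c(30, 56)), r = 7)
  g <- link_tracks(list(a, b))
  lk <- g$links[[1]]
  expect_equal(lk$to[order(lk$from)], c(1L, 2L))
})

test_that("process_stack turns a rendered stack into complete trajectories", {
  sched <- dosing_schedule(times = c(20, 80), concentrations = c(1e-9, 1e-7),
                           pre_drug_start = 0)
  out <- synth_trajectories(population_preset("low_variance"), sched,
                            kinetics_spec(tau = 10, noise_sd = 0), seed = 8,
                            cadence = 20, n_cells = 6)
  stk <- synth_image_stack(out$trajectories, seed = 8)
  res <- process_stack(stk$nuclear, stk$reporters, stk$times)
  expect_equal(sum(res$tracks$complete), 6L)
  got <- res$trajectories
  expect_equal(length(unique(got$cell_id[got$complete])), 6L)
  expect_error(process_stack(stk$nuclear[, , 1, drop = FALSE],
                             lapply(stk$reporters, function(a)
                               a[, , 1, drop = FALSE]),
                             stk$times[1]),
               class = "scdose_invalid_input")
})
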