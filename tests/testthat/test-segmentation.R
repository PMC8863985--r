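# shared scaffolding: a 20^3 grid of 2 mm voxels centred on the origin with
# two or three disjoint waypoint boxes along y
seg_affine <- function() affine_scale(2, c(-19, -19, -19))

two_box_def <- function(name = "B", prob = NULL, exclude = NULL) {
  aff <- seg_affine()
  dims <- c(20L, 20L, 20L)
  w1 <- waypoint_roi(box_mask(dims, aff, c(8, 3, 8), c(11, 5, 11)), 1)
  w2 <- waypoint_roi(box_mask(dims, aff, c(8, 14, 8), c(11, 16, 11)), 2)
  wps <- list(w1, w2)
  if (!is.null(exclude)) wps <- c(wps, list(exclude))
  bundle_definition(name, wps, probability_map = prob)
}

test_that("waypoint candidacy respects order, reversal and exclusions", {
  def <- two_box_def()
  s <- straight_streamline(c(0, -18, 0), c(0, 18, 0))
  v <- streamline_passes_waypoints(s, def)
  expect_true(v$candidate)
  expect_false(v$flipped)

  v_rev <- streamline_passes_waypoints(s[rev(seq_len(nrow(s))), ], def)
  expect_true(v_rev$candidate)
  expect_true(v_rev$flipped)

  # touches only the first box
  s_short <- straight_streamline(c(0, -18, 0), c(0, 0, 0))
  expect_false(streamline_passes_waypoints(s_short, def)$candidate)

  # misses both boxes laterally
  s_off <- straight_streamline(c(15, -18, 0), c(15, 18, 0))
  expect_false(streamline_passes_waypoints(s_off, def)$candidate)

  # an exclude waypoint on the path vetoes candidacy
  ex <- waypoint_roi(box_mask(c(20L, 20L, 20L), seg_affine(),
                              c(9, 9, 9), c(10, 10, 10)), 1, role = "exclude")
  def_ex <- two_box_def(exclude = ex)
  expect_false(streamline_passes_waypoints(s, def_ex)$candidate)
})

test_that("candidacy is invariant under reversal for random streamlines", {
  set.seed(17)
  def <- two_box_def()
  for (i in 1:20) {
    y <- seq(-18, 18, length.out = 40)
    s <- cbind(2 * sin(y / 5 + runif(1, 0, 2 * pi)) * runif(1, 0, 2),
               y, 2 * cos(y / 7) * runif(1, 0, 2))
    v1 <- streamline_passes_waypoints(s, def)
    v2 <- streamline_passes_waypoints(s[rev(seq_len(nrow(s))), ], def)
    expect_identical(v1$candidate, v2$candidate)
    if (v1$candidate) expect_identical(v1$flipped, !v2$flipped)
  }
})

test_that("probabilistic resolution picks the stronger atlas and warns on ties", {
  aff <- seg_affine()
  dims <- c(20L, 20L, 20L)
  mk_prob <- function(p) scalar_volume(array(p, dims), aff)
  defA <- two_box_def("A", prob = mk_prob(0.8))
  defB <- two_box_def("B", prob = mk_prob(0.2))
  atlas <- bundle_atlas(list(defA, defB), aff, space = "subject")
  s <- straight_streamline(c(0, -18, 0), c(0, 18, 0))
  set <- streamline_set(list(s))
  expect_identical(resolve_candidates(list(c("A", "B")), set, atlas), "A")
  expect_identical(resolve_candidates(list("B"), set, atlas), "B")
  expect_identical(resolve_candidates(list(character(0)), set, atlas),
                   NA_character_)
  atlas_tie <- bundle_atlas(list(two_box_def("A", prob = mk_prob(0.5)),
                                 two_box_def("B", prob = mk_prob(0.5))),
                            aff, space = "subject")
  expect_warning(out <- resolve_candidates(list(c("B", "A")), set, atlas_tie),
                 "tie")
  expect_identical(out, "A")  # lexicographic tie-break
})

test_that("cleaning removes planted outliers and is idempotent", {
  set.seed(42)
  mk <- function(off) straight_streamline(c(off[1], -25 + off[2], off[3]),
                                          c(off[1], 25 + off[2], off[3]), 30)
  streams <- lapply(1:20, function(i) mk(rnorm(3, 0, 0.5)))
  streams[[21]] <- mk(c(25, 0, 0))  # far lateral outlier
  set <- streamline_set(streams)
  b <- segmented_bundle("T", 1:21, rep(FALSE, 21))
  bc <- clean_bundle(b, set)
  expect_identical(length(bc$member_indices), 20L)
  expect_identical(bc$n_removed_cleaning, 1L)
  expect_false(21L %in% bc$member_indices)
  # idempotent: cleaning an already-clean bundle removes nothing
  bc2 <- clean_bundle(bc, set)
  expect_identical(bc2$member_indices, bc$member_indices)
  expect_identical(bc2$n_removed_cleaning, bc$n_removed_cleaning)
  # infinite threshold leaves the bundle unchanged
  b_inf <- clean_bundle(b, set, max_gauss_dist = Inf)
  expect_identical(b_inf$member_indices, b$member_indices)
})

test_that("cleaning keeps identical members and skips tiny bundles", {
  s <- straight_streamline(c(0, -20, 0), c(0, 20, 0), 25)
  set <- streamline_set(lapply(1:8, function(i) s + 0))
  b <- segmented_bundle("T", 1:8, rep(FALSE, 8))
  bc <- clean_bundle(b, set)
  expect_identical(length(bc$member_indices), 8L)  # distance 0 everywhere
  b_small <- segmented_bundle("T", 1:3, rep(FALSE, 3))
  expect_warning(bs <- clean_bundle(b_small, set), "< 5 members")
  expect_identical(bs$member_indices, 1:3)
})

test_that("bundle rasterisation counts voxels as hand-computed", {
  aff <- affine_scale(1, c(0, 0, 0))  # 1 mm voxels, centre of voxel k at k
  ref <- scalar_volume(array(0, c(12, 12, 12)), aff)
  set <- streamline_set(list(
    straight_streamline(c(2, 5, 5), c(6, 5, 5), n = 30),   # voxels x = 2..6
    straight_streamline(c(1, 8, 8), c(10, 8, 8), n = 2)))  # 2-point, 10 voxels
  b1 <- segmented_bundle("a", 1L, FALSE)
  m1 <- bundle_to_mask(b1, set, ref)
  expect_identical(sum(m1$grid), 5L)
  b2 <- segmented_bundle("b", 2L, FALSE)
  m2 <- bundle_to_mask(b2, set, ref)  # densification must fill all 10
  expect_identical(sum(m2$grid), 10L)
  empty <- bundle_to_mask(segmented_bundle("e"), set, ref)
  expect_identical(sum(empty$grid), 0L)
})

test_that("dice coefficient matches direct voxel counts", {
  aff <- affine_scale(2)
  dims <- c(10L, 10L, 10L)
  A <- box_mask(dims, aff, c(0, 0, 0), c(1, 1, 1))       # 8 voxels
  B <- box_mask(dims, aff, c(1, 1, 0), c(2, 1, 1))       # 4 voxels, overlap 2
  d <- dice_coefficient(A, B)
  expect_identical(d$n_A, 8L)
  expect_identical(d$n_B, 4L)
  expect_identical(d$n_intersection, 2L)
  expect_equal(d$value, 1 / 3)
  expect_equal(dice_coefficient(A, A)$value, 1)
  C <- box_mask(dims, aff, c(7, 7, 7), c(8, 8, 8))
  expect_equal(dice_coefficient(A, C)$value, 0)
  empty <- binary_mask(array(FALSE, dims), aff)
  expect_warning(d0 <- dice_coefficient(empty, empty), "empty")
  expect_equal(d0$value, 0)
  other <- box_mask(c(9L, 9L, 9L), aff, c(0, 0, 0), c(1, 1, 1))
  expect_error(dice_coefficient(A, other), "different grids")
})

test_that("atlas transforms resample ROIs as expected", {
  aff <- affine_scale(2, c(-9, -9, -9))
  dims <- c(10L, 10L, 10L)
  ref <- scalar_volume(array(0, dims), aff)
  box <- box_mask(dims, aff, c(3, 3, 3), c(5, 5, 5))
  pm <- scalar_volume(array(runif(prod(dims)), dims), aff)
  def <- bundle_definition("X", list(
    waypoint_roi(box, 1),
    waypoint_roi(box_mask(dims, aff, c(7, 7, 7), c(8, 8, 8)), 2)), pm)
  atlas <- bundle_atlas(list(def), aff)

  ident <- transform_rois_to_subject(atlas, diag(4), ref)
  expect_identical(ident$definitions[["X"]]$waypoints[[1]]$mask$grid, box$grid)

  # pure +2 mm translation in x shifts the box one voxel at 2 mm resolution
  xfm <- diag(4); xfm[1, 4] <- 2
  moved <- transform_rois_to_subject(atlas, xfm, ref)
  shifted <- array(FALSE, dims)
  shifted[5:7, 4:6, 4:6] <- TRUE
  expect_identical(moved$definitions[["X"]]$waypoints[[1]]$mask$grid, shifted)

  # 1.2x scaling grows a larger ROI's volume by about 1.2^3 (up to
  # nearest-neighbour quantisation of the box faces)
  big <- box_mask(dims, aff, c(2, 2, 2), c(7, 7, 7))
  atlas_big <- bundle_atlas(list(bundle_definition("Y", list(
    waypoint_roi(big, 1),
    waypoint_roi(box_mask(dims, aff, c(8, 8, 8), c(9, 9, 9)), 2)), pm)), aff)
  xfm_s <- diag(c(1.2, 1.2, 1.2, 1))
  grown <- transform_rois_to_subject(atlas_big, xfm_s, ref)
  ratio <- sum(grown$definitions[["Y"]]$waypoints[[1]]$mask$grid) / sum(big$grid)
  expect_gt(ratio, 1.2^3 * 0.7)
  expect_lt(ratio, 1.2^3 * 1.45)
  expect_error(transform_rois_to_subject(atlas, NULL, ref), "missing")
})

test_that("phantom segmentation is a partition that matches ground truth", {
  sp <- small_phantom()
  lab <- sp$ph$truth$labels
  all_members <- unlist(lapply(sp$bundles, function(b) b$member_indices))
  expect_identical(anyDuplicated(all_members), 0L)  # partition
  for (nm in names(sp$bundles)) {
    idx <- sp$bundles[[nm]]$member_indices
    expect_true(all(lab[idx] == nm))
  }
  planted <- sum(!is.na(lab))
  recovered <- sum(vapply(names(sp$bundles), function(nm)
    sum(lab[sp$bundles[[nm]]$member_indices] == nm), integer(1)))
  expect_gte(recovered / planted, 0.99)
  distractor_idx <- which(is.na(lab))
  assigned_distractors <- sum(distractor_idx %in% all_members)
  expect_lte(assigned_distractors / length(distractor_idx), 0.05)
})

test_that("recovered bundles overlap ground-truth masks with dice >= 0.95", {
  sp <- small_phantom()
  ref <- sp$ph$sessions[[1]]$r1
  lab <- sp$ph$truth$labels
  for (nm in names(sp$bundles)) {
    truth_b <- segmented_bundle(nm, which(!is.na(lab) & lab == nm))
    d <- dice_coefficient(
      bundle_to_mask(sp$bundles[[nm]], sp$ph$streamlines, ref),
      bundle_to_mask(truth_b, sp$ph$streamlines, ref))
    expect_gte(d$value, 0.95)
  }
})

test_that("segmentation is deterministic given identical inputs", {
  sp <- small_phantom()
  again <- segment_all(sp$ph$streamlines, sp$ph$atlas)
  expect_identical(lapply(again, function(b) b$member_indices),
                   lapply(sp$bundles, function(b) b$member_indices))
  # and an input with no candidates yields 24 empty bundles, not errors
  far <- streamline_set(list(straight_streamline(c(70, 70, 70),
                                                 c(75, 75, 75))))
  empty <- segment_all(far, sp$ph$atlas)
  expect_identical(length(empty), 24L)
  expect_true(all(vapply(empty, function(b)
    length(b$member_indices) == 0L, logical(1))))
})
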