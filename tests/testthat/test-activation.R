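# Activation gradient model: fitting, anchors, scoring geometry.

# z-scores with a planted latent structure: a dominant common-mode axis plus
# an activation contrast (CD69/OX40 up, LAG3/TIM3 down).
latent_fixture <- function(n = 2000, seed = 1, common_sd = 2, act_sd = 1,
                           noise_sd = 0.3) {
  set.seed(seed)
  u <- rep(1, 4) / 2                       # common mode
  v <- c(0.6, 0.4, -0.4, -0.6)
  v <- v / sqrt(sum(v^2))                  # activation contrast
  common <- rnorm(n, 0, common_sd)
  act <- rnorm(n, 0, act_sd)
  z <- outer(common, u) + outer(act, v) +
    matrix(rnorm(n * 4, 0, noise_sd), n, 4)
  colnames(z) <- tilax_activation_markers()
  list(z = z, act = act, v = v)
}

test_that("common-mode data keeps PC1 common and fits without warning", {
  fx <- latent_fixture()
  expect_no_warning(m <- activation_model(fx$z))
  expect_equal(m$component_indices, c(2L, 3L))
  r1 <- m$rotation[, 1]
  expect_true(all(r1 > 0) || all(r1 < 0))
})

test_that("refitting the same data reproduces identical anchors", {
  fx <- latent_fixture(seed = 2)
  m1 <- activation_model(fx$z)
  m2 <- activation_model(fx$z)
  expect_identical(m1$anchor_active, m2$anchor_active)
  expect_identical(m1$anchor_exhausted, m2$anchor_exhausted)
  expect_identical(m1$loadings, m2$loadings)
})

test_that("the recovered active anchor aligns with the planted CD69 direction", {
  # two planted contrast axes so the retained plane is a signal plane:
  # activation (CD69/OX40 vs TIM3/LAG3) plus a LAG3-specific contrast
  set.seed(3)
  n <- 3000
  u <- rep(1, 4) / 2
  v <- c(0.6, 0.4, -0.4, -0.6); v <- v / sqrt(sum(v^2))
  w <- c(0.2, -0.4, 0.8, -0.4); w <- w - sum(w * v) * v - sum(w * u) * u
  w <- w / sqrt(sum(w^2))
  z <- outer(rnorm(n, 0, 2.5), u) + outer(rnorm(n, 0, 1.2), v) +
    outer(rnorm(n, 0, 0.8), w) + matrix(rnorm(n * 4, 0, 0.15), n, 4)
  colnames(z) <- tilax_activation_markers()
  m <- activation_model(z)
  # the fitted anchor, mapped back to 4-d marker space, should align with
  # the projection of the CD69 axis onto the planted signal plane
  B <- cbind(v, w)
  e_cd69 <- c(1, 0, 0, 0)
  true4 <- B %*% crossprod(B, e_cd69)
  true4 <- true4 / sqrt(sum(true4^2))
  a4 <- as.numeric(m$loadings %*% m$anchor_active)
  ang <- acos(min(1, abs(sum(a4 * true4))))
  expect_lt(ang * 180 / pi, 10)
})

test_that("rank-deficient input names the offending column", {
  z <- latent_fixture(n = 50)$z
  z[, "LAG3"] <- 1
  expect_error(activation_model(z), "LAG3")
})

test_that("too few cells or bad marker order are rejected", {
  z <- latent_fixture(n = 9)$z
  expect_error(activation_model(z), "at least 10")
  fx <- latent_fixture(n = 100)
  m <- activation_model(fx$z)
  bad <- fx$z[, c(1, 2, 3, 4)]
  colnames(bad) <- c("CD69", "OX40", "LAG3", "XXX")
  expect_error(predict(m, bad), "mismatch|missing")
})

test_that("anchor points score exactly +1 / -1 and the centroid scores 0", {
  fx <- latent_fixture(seed = 4)
  m <- activation_model(fx$z)
  on_plane <- function(w) m$center + as.numeric(m$loadings %*% (m$centroid + w))
  z_pts <- rbind(on_plane(2.5 * m$anchor_active),
                 on_plane(0.7 * m$anchor_exhausted),
                 on_plane(c(0, 0)))
  colnames(z_pts) <- m$marker_order
  s <- predict(m, z_pts)
  expect_equal(s, c(1, -1, 0))
})

test_that("scores are radius-invariant and 0 on the angular bisector", {
  fx <- latent_fixture(seed = 5)
  m <- activation_model(fx$z)
  th_a <- atan2(m$anchor_active[2], m$anchor_active[1])
  th_e <- atan2(m$anchor_exhausted[2], m$anchor_exhausted[1])
  delta <- tilax:::wrap_pi(th_e - th_a)
  mid <- th_a + delta / 2
  dir <- c(cos(mid), sin(mid))
  on_plane <- function(w) m$center + as.numeric(m$loadings %*% (m$centroid + w))
  z_pts <- rbind(on_plane(0.3 * dir), on_plane(4 * dir),
                 on_plane(0.1 * m$anchor_active), on_plane(7 * m$anchor_active))
  colnames(z_pts) <- m$marker_order
  s <- predict(m, z_pts)
  expect_equal(s[1], 0, tolerance = 1e-12)
  expect_equal(s[2], 0, tolerance = 1e-12)
  expect_equal(s[3], s[4])                 # radial invariance
})

test_that("planted functional classes are ordered along the score", {
  sc <- scored_cohort(n_patients = 6, seed = 8)
  idx <- match(sc$cells$cell_id, sc$truth$cell_truth$cell_id)
  cls <- sc$truth$cell_truth$functional_class[idx]
  act <- sc$cells$activation
  m_active <- mean(act[cls == "active"], na.rm = TRUE)
  m_trans <- mean(act[cls == "transition"], na.rm = TRUE)
  m_exh <- mean(act[cls == "exhausted"], na.rm = TRUE)
  expect_gt(m_active, m_trans)
  expect_gt(m_trans, m_exh)
  expect_true(all(act >= -1 & act <= 1, na.rm = TRUE))
})

test_that("the axis scoring strategy preserves anchor and centroid geometry", {
  fx <- latent_fixture(seed = 6)
  m <- activation_model(fx$z, method = "axis")
  on_plane <- function(w) m$center + as.numeric(m$loadings %*% (m$centroid + w))
  z_pts <- rbind(on_plane(c(0, 0)), on_plane(2 * m$anchor_active),
                 on_plane(2 * m$anchor_exhausted))
  colnames(z_pts) <- m$marker_order
  s <- predict(m, z_pts)
  expect_equal(s[1], 0)
  expect_gt(s[2], 0.8)
  expect_lt(s[3], -0.8)
})

test_that("non-common-mode data triggers the documented fallback", {
  set.seed(7)
  n <- 500
  v <- c(1, 1, -1, -1) / 2
  z <- outer(rnorm(n, 0, 2), v) + matrix(rnorm(n * 4, 0, 0.4), n, 4)
  colnames(z) <- tilax_activation_markers()
  expect_warning(m <- activation_model(z), "fall")
  expect_length(m$component_indices, 2)
})
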