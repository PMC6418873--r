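test_that("eigendecomposition recovers constructed spectra", {
  expect_equal(eigendecompose_voxel(diag(3)), c(1, 1, 1))
  expect_equal(eigendecompose_voxel(diag(c(2, 1, 1))), c(2, 1, 1))
  set.seed(42)
  for (r in 1:20) {
    t <- random_spd(c(3, 2, 1))
    expect_equal(eigendecompose_voxel(t), c(3, 2, 1), tolerance = 1e-8)
  }
  bad <- diag(3); bad[1, 2] <- 1e-3
  expect_error(eigendecompose_voxel(bad), "asymmetric")
})

test_that("FA matches the closed form and its limits", {
  expect_equal(fa_from_eigenvalues(c(1, 1, 1)), 0)
  expect_equal(fa_from_eigenvalues(c(1, 0, 0)), 1)
  expect_equal(fa_from_eigenvalues(c(2, 1, 1)), 1 / sqrt(6), tolerance = 1e-12)
  expect_equal(fa_from_eigenvalues(c(0, 0, 0)), 0)  # background convention
  expect_error(fa_from_eigenvalues(c(1, 1, -0.1)), "negative")
  # scale invariance, property-style
  set.seed(7)
  for (r in 1:50) {
    lam <- sort(runif(3, 0, 2), decreasing = TRUE)
    c_ <- runif(1, 0.01, 100)
    expect_equal(fa_from_eigenvalues(lam * c_), fa_from_eigenvalues(lam),
                 tolerance = 1e-10)
  }
})

test_that("MD/AD/RD definitions and ordering", {
  expect_equal(md_ad_rd_from_eigenvalues(c(2, 1, 1)),
               c(MD = 4 / 3, AD = 2, RD = 1))
  expect_equal(md_ad_rd_from_eigenvalues(c(1, 1, 1)),
               c(MD = 1, AD = 1, RD = 1))
  expect_error(md_ad_rd_from_eigenvalues(c(1, 2, 3)), "sorted")
  set.seed(11)
  for (r in 1:1000) {
    lam <- sort(runif(3, 0, 5), decreasing = TRUE)
    v <- md_ad_rd_from_eigenvalues(lam)
    expect_true(v["AD"] >= v["MD"] && v["MD"] >= v["RD"])
  }
})

test_that("scalar maps: identity field, range, background", {
  shape <- c(4, 5, 4)
  tf <- array(0, c(shape, 6))
  tf[, , , 1] <- 1; tf[, , , 4] <- 1; tf[, , , 6] <- 1  # identity tensors
  sm <- scalar_maps_from_field(tf)
  expect_true(all(sm$FA == 0))
  expect_true(all(abs(sm$MD - 1) < 1e-12))
  # background zero tensors -> all four zero
  tf0 <- array(0, c(shape, 6))
  sm0 <- scalar_maps_from_field(tf0)
  for (k in c("FA", "MD", "AD", "RD")) expect_true(all(sm0[[k]] == 0))
})

test_that("scalar maps are rotation invariant and FA stays in [0,1]", {
  set.seed(3)
  shape <- c(3, 3, 3)
  lam <- matrix(runif(prod(shape) * 3, 0, 2), ncol = 3)
  tf <- array(0, c(shape, 6)); tfr <- array(0, c(shape, 6))
  for (v in seq_len(prod(shape))) {
    l <- sort(lam[v, ], decreasing = TRUE)
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    t1 <- diag(l)
    t2 <- q %*% diag(l) %*% t(q)
    idx <- arrayInd(v, shape)
    tf[idx[1], idx[2], idx[3], ] <- t1[c(1, 2, 3, 5, 6, 9)][c(1, 2, 3, 4, 5, 6)]
    tf[idx[1], idx[2], idx[3], ] <- c(t1[1, 1], t1[1, 2], t1[1, 3],
                                      t1[2, 2], t1[2, 3], t1[3, 3])
    tfr[idx[1], idx[2], idx[3], ] <- c(t2[1, 1], t2[1, 2], t2[1, 3],
                                       t2[2, 2], t2[2, 3], t2[3, 3])
  }
  s1 <- scalar_maps_from_field(tf)
  s2 <- scalar_maps_from_field(tfr)
  for (k in c("FA", "MD", "AD", "RD"))
    expect_equal(s1[[k]], s2[[k]], tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(min(s1$FA) >= 0 && max(s1$FA) <= 1)
})

test_that("tensor-field NIfTI round trip", {
  set.seed(5)
  tf <- array(rnorm(4 * 4 * 4 * 6), c(4, 4, 4, 6))
  tf <- tf + aperm(array(0, c(4, 4, 4, 6)), c(1, 2, 3, 4))  # keep as is
  p <- tempfile(fileext = ".nii.gz")
  write_tensor_field(tf, p)
  back <- read_tensor_field(p)
  expect_equal(as.vector(back), as.vector(tf))
  # a 3D file is not a tensor field
  p3 <- tempfile(fileext = ".nii.gz")
  write_nifti(array(0, c(4, 4, 4)), p3)
  expect_error(read_tensor_field(p3), "6-component")
})
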