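test_that("healthy and normal phantoms carry no lesions and valid pixels", {
  f <- generate_fundus_phantom(phantom_config("fundus", 32, grade = "healthy",
                                              subject_id = 1, seed = 1))
  o <- generate_oct_phantom(phantom_config("oct", 32, grade = "normal",
                                           subject_id = 1, seed = 1))
  expect_true(all(f$lesion_counts == 0))
  expect_true(all(o$lesion_counts == 0))
  expect_true(all(f$pixels >= 0 & f$pixels <= 1))
  expect_true(all(o$pixels >= 0 & o$pixels <= 1))
  expect_equal(dim(f$pixels), c(32, 32, 3))
  expect_equal(dim(o$pixels), c(32, 32))
})

test_that("generation is deterministic and subject identity is stable across grades", {
  cfg <- phantom_config("fundus", 32, grade = "moderate", subject_id = 7, seed = 3)
  a <- generate_fundus_phantom(cfg)
  b <- generate_fundus_phantom(cfg)
  expect_identical(a$pixels, b$pixels)
  # same subject, different grade/seed: vessel tree and disc unchanged ->
  # pixels agree wherever neither image carries a lesion
  c2 <- generate_fundus_phantom(phantom_config("fundus", 32, grade = "healthy",
                                               subject_id = 7, seed = 99))
  les <- Reduce(`|`, lapply(a$lesion_mask, function(m) m > 0))
  # compare the green channel away from lesions (noise differs, structure not)
  diff <- abs(a$pixels[, , 2] - c2$pixels[, , 2])
  expect_lt(max(diff[!les]), 0.1)   # only pixel noise differs off-lesion
})

test_that("invalid grades and sizes are rejected", {
  expect_error(phantom_config("fundus", 32, grade = "CNV"), "invalid grade")
  expect_error(phantom_config("oct", 32, grade = "severe"), "invalid grade")
  expect_error(phantom_config("fundus", 16), "image_size")
})

test_that("lesion burden grows with severity (Monte-Carlo over count draws)", {
  draws <- function(grade, n = 200) {
    out <- matrix(0L, n, 3)
    withr::with_seed(42, {
      for (i in seq_len(n)) out[i, ] <- retinocf:::sample_lesion_counts(grade)
    })
    colMeans(out)
  }
  m_mild <- draws("mild")
  m_mod <- draws("moderate")
  m_sev <- draws("severe")
  expect_true(all(m_mod > m_mild))   # every lesion type
  expect_true(all(m_sev >= m_mod))
})

test_that("OCT disease classes show their defining structure", {
  # drusen: RPE boundary elevation variance exceeds normal's
  v_norm <- v_dru <- numeric(40)
  for (s in 1:40) {
    nrm <- generate_oct_phantom(phantom_config("oct", 32, grade = "normal",
                                               subject_id = s, seed = s))
    dru <- generate_oct_phantom(phantom_config("oct", 32, grade = "drusen",
                                               subject_id = s, seed = s))
    v_norm[s] <- stats::var(nrm$boundary)
    v_dru[s] <- stats::var(dru$boundary)
  }
  expect_gt(mean(v_dru > v_norm), 0.95)
  expect_gt(mean(v_dru), mean(v_norm))
  # DME: at least one cavity component in the mask
  dme <- generate_oct_phantom(phantom_config("oct", 32, grade = "DME",
                                             subject_id = 3, seed = 5))
  expect_gte(dme$lesion_counts[["cavity"]], 1L)
  expect_gt(sum(dme$lesion_mask$cavity), 0)
})

test_that("lesion masks are consistent with counts under 8-connectivity", {
  for (s in 1:5) {
    im <- generate_fundus_phantom(phantom_config("fundus", 32, grade = "severe",
                                                 subject_id = s, seed = s))
    for (ty in names(im$lesion_mask)) {
      cc <- retinocf:::count_components(im$lesion_mask[[ty]] > 0, 1L)
      expect_equal(cc$n, unname(im$lesion_counts[[ty]]))
    }
  }
})

test_that("the lesion oracle reproduces ground truth on generator output", {
  # fidelity bar: >= 99% exact matches over 500 images across modalities
  n_ok <- 0L; n_tot <- 0L
  for (mod in c("fundus", "oct")) {
    classes <- if (mod == "fundus") fundus_grades() else oct_classes()
    for (g in classes) {
      for (s in 1:28) {
        im <- generate_phantom(phantom_config(mod, 32, grade = g,
                                              subject_id = s, seed = 1000 + s))
        n_tot <- n_tot + 1L
        if (all(lesion_oracle(im$pixels, mod) == im$lesion_counts)) n_ok <- n_ok + 1L
      }
    }
  }
  expect_gte(n_tot, 250L)
  expect_gte(n_ok / n_tot, 0.99)
})

test_that("oracle handles blank and hand-stamped images", {
  blank <- array(0, dim = c(32, 32, 3))
  expect_true(all(lesion_oracle(blank, "fundus") == 0))
  expect_error(lesion_oracle(matrix(0, 32, 32), "fundus"), "H x W x 3")
  # stamp three microaneurysm disks onto a background-coloured field
  pal <- phantom_palette()
  img <- array(rep(pal$fundus_bg, each = 32 * 32), dim = c(32, 32, 3))
  for (ctr in list(c(8, 8), c(16, 24), c(26, 12))) {
    sel <- retinocf:::disc_mask(32, ctr[1], ctr[2], 1)
    for (ch in 1:3) { p <- img[, , ch]; p[sel] <- pal$microaneurysm[ch]; img[, , ch] <- p }
  }
  expect_equal(unname(lesion_oracle(img, "fundus")[["microaneurysm"]]), 3L)
})

test_that("datasets split subject-wise and honour class counts", {
  ds <- generate_dataset(n_per_class = 10, images_per_subject = 2,
                         split_fractions = c(0.75, 0.15, 0.10),
                         seed = 5, modality = "fundus", image_size = 32)
  expect_length(ds$images, 10 * 5)
  # no subject in two splits
  tab <- table(ds$subject_id, ds$split)
  expect_true(all(rowSums(tab > 0) == 1))
  # both images of a subject share the vessel tree (off-lesion green channel)
  sid <- ds$subject_id[duplicated(ds$subject_id)][1]
  pair <- which(ds$subject_id == sid)[1:2]
  a <- ds$images[[pair[1]]]; b <- ds$images[[pair[2]]]
  les <- Reduce(`|`, c(lapply(a$lesion_mask, function(m) m > 0),
                       lapply(b$lesion_mask, function(m) m > 0)))
  diff <- abs(a$pixels[, , 2] - b$pixels[, , 2])
  expect_lt(max(diff[!les]), 0.1)
  expect_error(generate_dataset(10, split_fractions = c(0.5, 0.2, 0.2)),
               "sum to 1")
})

test_that("oversampling balances the training split with pixel-identical duplicates", {
  ds <- generate_dataset(n_per_class = 8, seed = 2, modality = "fundus",
                         image_size = 32)
  # unbalance by dropping some referable training images
  drop <- which(ds$split == "train" & ds$label == 4)[1:4]
  keep <- setdiff(seq_along(ds$images), drop)
  ds$images <- ds$images[keep]; ds$split <- ds$split[keep]
  ds$label <- ds$label[keep]; ds$subject_id <- ds$subject_id[keep]
  bal <- balance_by_oversampling(ds)
  tab <- table(bal$label[bal$split == "train"])
  expect_true(all(tab == max(tab)))
  # non-train entries untouched
  expect_equal(sum(bal$split != "train"), sum(ds$split != "train"))
  # duplicates are pixel-identical to originals
  extra <- setdiff(seq_along(bal$images), seq_along(ds$images))
  for (i in extra[1]) {
    orig <- which(vapply(seq_along(ds$images), function(j)
      identical(ds$images[[j]]$pixels, bal$images[[i]]$pixels), TRUE))
    expect_gte(length(orig), 1L)
  }
  # already balanced input returns identical sizes
  bal2 <- balance_by_oversampling(bal)
  expect_length(bal2$images, length(bal$images))
})
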