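# Synthetic retina phantoms: fundus-like RGB images across the five diabetic
# retinopathy grades, and OCT-B-scan-like grayscale images across the four
# OCT classes. Each image carries ground-truth lesion masks and counts, a
# subject identity (vessel tree / layer geometry shared across a subject's
# images), and renders with intensity signatures that the lesion oracle is
# calibrated against.

#' Fundus grading classes (increasing severity)
#' @return Character vector of the five diabetic retinopathy grades.
#' @export
fundus_grades <- function() c("healthy", "mild", "moderate", "severe", "proliferative")

#' OCT classes
#' @return Character vector of the four OCT classes.
#' @export
oct_classes <- function() c("normal", "CNV", "drusen", "DME")

fundus_lesion_types <- function() c("microaneurysm", "hemorrhage", "exudate")
oct_lesion_types <- function() c("drusen", "cavity", "cnv")

# Mean lesion counts per grade. Monotone non-decreasing in severity for every
# lesion type; diseased grades always render at least one microaneurysm so
# that disease presence is unambiguous. These are generator parameters.
fundus_count_means <- function() {
  m <- rbind(healthy       = c(0,   0,   0),
             mild          = c(1.5, 0,   0),
             moderate      = c(4,   1.5, 1.5),
             severe        = c(7,   3,   2.5),
             proliferative = c(9,   5,   3.5))
  colnames(m) <- fundus_lesion_types()
  m
}

#' Rendering palette and oracle thresholds
#'
#' Colours used by the phantom renderer and the matching detection thresholds
#' used by [lesion_oracle()]. Fundus lesions carry intensity signatures
#' (very dark red dots/blobs for microaneurysms and hemorrhages, bright
#' yellow blobs for exudates) that are separable from vessels and the optic
#' disc by fixed thresholds; OCT lesion classes occupy disjoint intensity
#' windows relative to the retinal bands.
#'
#' @return Named list of colour vectors and scalar thresholds.
#' @export
phantom_palette <- function() {
  list(
    fundus_bg      = c(0.72, 0.35, 0.12),
    vessel         = c(0.35, 0.15, 0.08),
    disc           = c(0.95, 0.85, 0.55),
    microaneurysm  = c(0.25, 0.05, 0.04),
    hemorrhage     = c(0.28, 0.06, 0.05),
    exudate        = c(0.97, 0.92, 0.35),
    outside        = 0.02,
    noise_sd       = 0.008,
    dark_green_thr = 0.10,   # green channel below this = dark lesion
    dark_min_px    = 2L,
    dark_area_split = 12L,   # components larger than this are hemorrhages
    exudate_thr    = c(r = 0.85, g = 0.80, b = 0.45),
    oct_band       = c(vitreous = 0.05, nfl = 0.35, inner = 0.18,
                       outer = 0.40, onl = 0.22, rpe = 0.80, below = 0.08),
    oct_noise_sd   = 0.012,
    oct_drusen_int = 0.97, oct_drusen_thr = 0.89,
    oct_cavity_int = 0.03, oct_cavity_thr = 0.12,
    oct_cnv_int    = 0.55, oct_cnv_thr = 0.30
  )
}

#' Phantom configuration
#'
#' @param modality `"fundus"` or `"oct"`.
#' @param image_size Pixels per side (square image), at least 32.
#' @param grade Class name: one of [fundus_grades()] for fundus or
#'   [oct_classes()] for OCT.
#' @param subject_id Integer subject identity; images sharing a `subject_id`
#'   share their vessel tree and optic-disc position (fundus) or layer
#'   geometry (OCT) across grades and seeds.
#' @param seed Integer seed controlling lesion placement and pixel noise.
#' @param n_vessel_branches Number of main vessel branches (fundus).
#' @param vessel_wiggle Standard deviation (radians) of the per-step heading
#'   change of the vessel random walk.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(modality = c("fundus", "oct"), image_size = 64L,
                           grade = NULL, subject_id = 1L, seed = 1L,
                           n_vessel_branches = 5L, vessel_wiggle = 0.18) {
  modality <- match.arg(modality)
  classes <- if (modality == "fundus") fundus_grades() else oct_classes()
  if (is.null(grade)) grade <- classes[1L]
  if (!grade %in% classes) {
    stop("invalid grade '", grade, "' for modality '", modality,
         "'; expected one of: ", paste(classes, collapse = ", "))
  }
  if (image_size < 32L) stop("image_size must be at least 32")
  structure(list(modality = modality, image_size = as.integer(image_size),
                 grade = grade, subject_id = as.integer(subject_id),
                 seed = as.integer(seed),
                 n_vessel_branches = as.integer(n_vessel_branches),
                 vessel_wiggle = vessel_wiggle),
            class = "phantom_config")
}

subject_seed <- function(subject_id) {
  as.integer((as.numeric(subject_id) * 48271 + 11) %% 2147483629)
}

lesion_seed <- function(seed, subject_id) {
  as.integer((as.numeric(seed) * 69621 + as.numeric(subject_id) * 181 + 7) %%
               2147483629)
}

new_labeled_image <- function(pixels, label, grade, lesion_mask, lesion_counts,
                              subject_id, modality, boundary = NULL) {
  structure(list(pixels = pixels, label = label, grade = grade,
                 lesion_mask = lesion_mask, lesion_counts = lesion_counts,
                 subject_id = subject_id, modality = modality,
                 boundary = boundary),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<labeled_image> %s '%s' subject %d, %dx%d, lesions: %s\n",
              x$modality, x$grade, x$subject_id, d[1], d[2],
              paste(names(x$lesion_counts), x$lesion_counts,
                    sep = "=", collapse = " ")))
  invisible(x)
}

# --- fundus --------------------------------------------------------------

disc_mask <- function(n, cy, cx, r) {
  yy <- matrix(seq_len(n), n, n)
  xx <- matrix(seq_len(n), n, n, byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

# Seeded branching random walk anchored at the optic disc; returns a logical
# vessel mask. Geometry depends only on the subject RNG stream.
draw_vessels <- function(n, disc_c, fov_r, centre, n_branches, wiggle) {
  mask <- matrix(FALSE, n, n)
  base_ang <- atan2(centre[1] - disc_c[1], centre[2] - disc_c[2])
  queue <- list()
  for (b in seq_len(n_branches)) {
    ang <- base_ang + (b - (n_branches + 1) / 2) * 0.55 + stats::rnorm(1, 0, 0.15)
    queue[[length(queue) + 1L]] <- list(pos = disc_c, ang = ang,
                                        steps = round(n * stats::runif(1, 0.7, 1.1)))
  }
  while (length(queue)) {
    br <- queue[[1L]]; queue[[1L]] <- NULL
    pos <- br$pos; ang <- br$ang
    fork_at <- if (br$steps > 12) sample.int(br$steps - 6L, 1L) + 3L else -1L
    for (s in seq_len(br$steps)) {
      ang <- ang + stats::rnorm(1, 0, wiggle)
      pos <- pos + c(sin(ang), cos(ang))
      iy <- round(pos[1]); ix <- round(pos[2])
      if (iy < 1 || iy > n || ix < 1 || ix > n) break
      if ((iy - centre[1])^2 + (ix - centre[2])^2 > (0.97 * fov_r)^2) break
      mask[iy, ix] <- TRUE
      if (s == fork_at) {
        queue[[length(queue) + 1L]] <-
          list(pos = pos, ang = ang + sample(c(-1, 1), 1) * stats::runif(1, 0.5, 0.9),
               steps = round(br$steps * 0.6))
      }
    }
  }
  mask
}

# Sample lesion counts for a grade. Diseased grades render at least one
# microaneurysm; other types are Poisson draws at the grade mean.
sample_lesion_counts <- function(grade) {
  mu <- fundus_count_means()[grade, ]
  counts <- integer(length(mu)); names(counts) <- names(mu)
  for (ty in names(mu)) {
    m <- mu[[ty]]
    if (m <= 0) { counts[[ty]] <- 0L; next }
    counts[[ty]] <- if (ty == "microaneurysm") 1L + stats::rpois(1, m - 1)
                    else stats::rpois(1, m)
  }
  counts
}

# Place centres inside the field of view with pairwise separation; returns a
# matrix of (y, x, r) rows, possibly fewer than requested if space runs out.
place_lesions <- function(counts_radii, centre, fov_r, taken) {
  placed <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(counts_radii))) {
    r <- counts_radii[i, "r"]
    ok <- FALSE
    for (try in 1:200) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * (fov_r * 0.82 - r)
      y <- centre[1] + rad * sin(ang); x <- centre[2] + rad * cos(ang)
      all_pts <- rbind(taken, placed)
      if (nrow(all_pts) == 0 ||
          all(sqrt((all_pts[, 1] - y)^2 + (all_pts[, 2] - x)^2) >
                all_pts[, 3] + r + 2)) { ok <- TRUE; break }
    }
    if (ok) placed <- rbind(placed, c(y, x, r))
  }
  placed
}

stamp_disk <- function(img, mask, y, x, r, col) {
  n <- dim(img)[1]
  sel <- disc_mask(n, y, x, r)
  for (ch in 1:3) { pl <- img[, , ch]; pl[sel] <- col[ch]; img[, , ch] <- pl }
  mask[sel] <- TRUE
  list(img = img, mask = mask)
}

#' Generate a fundus-like phantom image
#'
#' Renders a circular field of view with a radially shaded background, an
#' optic disc and a seeded branching vessel tree (both determined by
#' `subject_id` alone), then stamps grade-dependent lesions: dark
#' microaneurysm dots, larger dark hemorrhage blobs and bright exudates.
#' Deterministic given `(seed, subject_id)`.
#'
#' @param config A [phantom_config()] with `modality = "fundus"`.
#' @return A `labeled_image` with pixels in `[0,1]` (H x W x 3), per-type
#'   binary lesion masks, lesion counts and the subject id.
#' @export
generate_fundus_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"), config$modality == "fundus")
  n <- config$image_size
  pal <- phantom_palette()
  centre <- c(n / 2 + 0.5, n / 2 + 0.5)
  fov_r <- n / 2 - 1

  # subject-level geometry and tint
  geom <- withr::with_seed(subject_seed(config$subject_id), {
    disc_ang <- stats::runif(1, -0.6, 0.6) + sample(c(0, pi), 1)
    disc_c <- centre + 0.62 * fov_r * c(sin(disc_ang), cos(disc_ang))
    tint <- stats::rnorm(3, 0, 0.03)
    vess <- draw_vessels(n, disc_c, fov_r, centre,
                         config$n_vessel_branches, config$vessel_wiggle)
    list(disc_c = disc_c, tint = tint, vessels = vess)
  })

  yy <- matrix(seq_len(n), n, n)
  xx <- matrix(seq_len(n), n, n, byrow = TRUE)
  rad2 <- (yy - centre[1])^2 + (xx - centre[2])^2
  fov <- rad2 <= fov_r^2
  vignette <- 1 - 0.25 * rad2 / fov_r^2

  img <- array(pal$outside, dim = c(n, n, 3))
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[fov] <- pmin(1, pmax(0, (pal$fundus_bg[ch] + geom$tint[ch]) * vignette[fov]))
    img[, , ch] <- pl
  }
  disc_r <- 0.11 * n
  sel <- disc_mask(n, geom$disc_c[1], geom$disc_c[2], disc_r) & fov
  for (ch in 1:3) { pl <- img[, , ch]; pl[sel] <- pal$disc[ch]; img[, , ch] <- pl }
  vess <- geom$vessels & !sel
  for (ch in 1:3) { pl <- img[, , ch]; pl[vess] <- pal$vessel[ch]; img[, , ch] <- pl }

  # lesions
  types <- fundus_lesion_types()
  masks <- stats::setNames(lapply(types, function(t) matrix(FALSE, n, n)), types)
  radii <- c(microaneurysm = 1.0,
             hemorrhage = max(2.4, 0.05 * n),
             exudate = max(2.0, 0.042 * n))
  counts <- stats::setNames(integer(3), types)
  noise <- NULL
  withr::with_seed(lesion_seed(config$seed, config$subject_id), {
    want <- sample_lesion_counts(config$grade)
    # keep lesions away from the optic disc
    taken <- matrix(c(geom$disc_c, disc_r + 1), 1, 3)
    for (ty in types) {
      if (want[[ty]] == 0) next
      spec <- matrix(radii[[ty]], want[[ty]], 1,
                     dimnames = list(NULL, NULL))
      colnames(spec) <- "r"
      pl <- place_lesions(spec, centre, fov_r, taken)
      taken <- rbind(taken, pl)
      for (i in seq_len(nrow(pl))) {
        st <- stamp_disk(img, masks[[ty]], pl[i, 1], pl[i, 2], pl[i, 3], pal[[ty]])
        img <- st$img; masks[[ty]] <- st$mask
      }
      counts[[ty]] <- nrow(pl)
    }
    noise <- array(stats::rnorm(n * n * 3, 0, pal$noise_sd), dim = c(n, n, 3))
  })
  img <- clip_range(img + noise, 0, 1)

  new_labeled_image(img, label = match(config$grade, fundus_grades()),
                    grade = config$grade,
                    lesion_mask = lapply(masks, function(m) m * 1L),
                    lesion_counts = counts,
                    subject_id = config$subject_id, modality = "fundus")
}

# --- OCT -----------------------------------------------------------------

#' Generate an OCT-B-scan-like phantom image
#'
#' Renders stacked retinal bands with smooth, subject-specific boundary
#' elevation curves and a bright RPE band. Disease classes modify the
#' geometry: `drusen` adds dome-shaped bright sub-RPE deposits (bumpy RPE),
#' `DME` carves dark intraretinal cavities, and `CNV` adds a subretinal
#' membrane below a locally disrupted RPE.
#'
#' @param config A [phantom_config()] with `modality = "oct"`.
#' @return A `labeled_image` with grayscale pixels (H x W matrix), lesion
#'   masks/counts, and the RPE boundary curve in `$boundary`.
#' @export
generate_oct_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"), config$modality == "oct")
  n <- config$image_size
  pal <- phantom_palette()
  xs <- seq_len(n)

  elev <- withr::with_seed(subject_seed(config$subject_id), {
    a <- stats::rnorm(3, 0, 0.006 * n)
    ph <- stats::runif(3, 0, 2 * pi)
    a[1] * sin(2 * pi * xs / n + ph[1]) +
      a[2] * sin(4 * pi * xs / n + ph[2]) +
      a[3] * sin(6 * pi * xs / n + ph[3])
  })

  top <- 0.30 * n + elev
  b1 <- top + 0.06 * n
  b2 <- b1 + 0.10 * n
  b3 <- b2 + 0.12 * n
  rpe_top <- b3 + 0.05 * n
  rpe_bot <- rpe_top + max(2, 0.035 * n)

  types <- oct_lesion_types()
  masks <- stats::setNames(lapply(types, function(t) matrix(FALSE, n, n)), types)
  counts <- stats::setNames(integer(3), types)
  drusen_bump <- numeric(n)
  cavities <- matrix(numeric(0), 0, 3)
  cnv_col <- NA; cnv_w <- 0; cnv_h <- 0
  noise <- NULL
  withr::with_seed(lesion_seed(config$seed, config$subject_id), {
    if (config$grade == "drusen") {
      k <- 1L + stats::rpois(1, 2)
      cols <- sort(sample(seq(0.12 * n, 0.88 * n), k))
      # enforce spacing so bumps stay separate components
      keep <- c(TRUE, diff(cols) > 0.22 * n)
      cols <- cols[keep]
      for (cc in cols) {
        w <- stats::runif(1, 0.05, 0.075) * n
        h <- stats::runif(1, 0.05, 0.08) * n
        prof <- pmax(0, 1 - ((xs - cc) / w)^2) * h
        drusen_bump <- pmax(drusen_bump, prof)
      }
      counts[["drusen"]] <- length(cols)
    } else if (config$grade == "DME") {
      k <- 1L + stats::rpois(1, 1.2)
      placed <- matrix(numeric(0), 0, 3)
      for (i in seq_len(k)) {
        for (try in 1:100) {
          cx <- stats::runif(1, 0.15 * n, 0.85 * n)
          rx <- stats::runif(1, 0.05, 0.09) * n
          if (nrow(placed) == 0 ||
              all(abs(placed[, 1] - cx) > placed[, 2] + rx + 3)) {
            placed <- rbind(placed, c(cx, rx, stats::runif(1, 0.5, 0.8)))
            break
          }
        }
      }
      cavities <- placed
      counts[["cavity"]] <- nrow(placed)
    } else if (config$grade == "CNV") {
      cnv_col <- stats::runif(1, 0.25 * n, 0.75 * n)
      cnv_w <- stats::runif(1, 0.10, 0.16) * n
      cnv_h <- stats::runif(1, 0.10, 0.14) * n
      counts[["cnv"]] <- 1L
    }
    noise <- matrix(stats::rnorm(n * n, 0, pal$oct_noise_sd), n, n)
  })

  rpe_top_curve <- rpe_top - drusen_bump
  rpe_bot_curve <- rpe_bot
  if (config$grade == "CNV") {
    # RPE elevated over the membrane (both boundaries lifted)
    lift <- pmax(0, 1 - ((xs - cnv_col) / cnv_w)^2) * 0.4 * cnv_h
    rpe_top_curve <- rpe_top_curve - lift
    rpe_bot_curve <- rpe_bot - lift
  }

  img <- matrix(pal$oct_band[["vitreous"]], n, n)
  band <- pal$oct_band
  for (x in xs) {
    col <- rep(band[["vitreous"]], n)
    rows <- seq_len(n)
    col[rows >= top[x] & rows < b1[x]] <- band[["nfl"]]
    col[rows >= b1[x] & rows < b2[x]] <- band[["inner"]]
    col[rows >= b2[x] & rows < b3[x]] <- band[["outer"]]
    col[rows >= b3[x] & rows < rpe_top_curve[x]] <- band[["onl"]]
    col[rows >= rpe_top_curve[x] & rows < rpe_bot_curve[x]] <- band[["rpe"]]
    col[rows >= rpe_bot_curve[x]] <- band[["below"]]
    img[, x] <- col
  }

  # drusen deposits fill the dome between the raised RPE top and its baseline
  if (counts[["drusen"]] > 0) {
    for (x in xs) {
      if (drusen_bump[x] > 0.5) {
        rows <- which(seq_len(n) >= rpe_top_curve[x] & seq_len(n) < rpe_top[x])
        img[rows, x] <- pal$oct_drusen_int
        masks$drusen[rows, x] <- TRUE
      }
    }
  }
  if (counts[["cavity"]] > 0) {
    mid <- (b2 + b3) / 2
    for (i in seq_len(nrow(cavities))) {
      cx <- cavities[i, 1]; rx <- cavities[i, 2]
      ry <- max(2, 0.05 * n * cavities[i, 3])
      for (x in xs) {
        dx2 <- ((x - cx) / rx)^2
        if (dx2 < 1) {
          cy <- mid[x]
          rows <- which((((seq_len(n) - cy) / ry)^2 + dx2) <= 1)
          if (length(rows)) { img[rows, x] <- pal$oct_cavity_int
                              masks$cavity[rows, x] <- TRUE }
        }
      }
    }
  }
  if (counts[["cnv"]] > 0) {
    for (x in xs) {
      dx2 <- ((x - cnv_col) / cnv_w)^2
      if (dx2 < 1) {
        depth <- cnv_h * sqrt(1 - dx2)
        rows <- which(seq_len(n) >= rpe_bot_curve[x] &
                        seq_len(n) < rpe_bot[x] + depth)
        if (length(rows)) { img[rows, x] <- pal$oct_cnv_int
                            masks$cnv[rows, x] <- TRUE }
      }
    }
  }

  img <- clip_range(img + noise, 0, 1)
  new_labeled_image(img, label = match(config$grade, oct_classes()),
                    grade = config$grade,
                    lesion_mask = lapply(masks, function(m) m * 1L),
                    lesion_counts = counts,
                    subject_id = config$subject_id, modality = "oct",
                    boundary = rpe_top_curve)
}

#' Generate a phantom of either modality
#' @param config A [phantom_config()].
#' @return A `labeled_image`.
#' @export
generate_phantom <- function(config) {
  if (config$modality == "fundus") generate_fundus_phantom(config)
  else generate_oct_phantom(config)
}

# --- dataset -------------------------------------------------------------

#' Generate a subject-wise split phantom dataset
#'
#' Subjects are the unit of splitting: every image of a subject lands in the
#' same split, mirroring subject-wise partitioning of clinical datasets.
#' Each subject carries one class; images of a subject differ only in lesion
#' placement (same vessel tree / layer geometry).
#'
#' @param n_per_class Images per class.
#' @param images_per_subject Images generated for each subject.
#' @param split_fractions Named or positional fractions `(train, val, test)`
#'   summing to 1.
#' @param seed Integer seed.
#' @param modality,image_size Passed to [phantom_config()].
#' @return A `phantom_dataset`: list of `labeled_image`s plus parallel
#'   vectors `split`, `label`, `subject_id`.
#' @export
generate_dataset <- function(n_per_class = 50L, images_per_subject = 1L,
                             split_fractions = c(train = 0.75, val = 0.15, test = 0.10),
                             seed = 1L, modality = c("fundus", "oct"),
                             image_size = 64L) {
  modality <- match.arg(modality)
  if (abs(sum(split_fractions) - 1) > 1e-8) {
    stop("split_fractions must sum to 1")
  }
  if (length(split_fractions) != 3L) stop("need three split fractions (train, val, test)")
  classes <- if (modality == "fundus") fundus_grades() else oct_classes()
  n_subj_per_class <- ceiling(n_per_class / images_per_subject)

  images <- list(); split <- character(); labels <- integer(); subjects <- integer()
  next_subject <- 1L
  withr::with_seed(seed, {
    for (ci in seq_along(classes)) {
      subj_ids <- seq(next_subject, length.out = n_subj_per_class)
      next_subject <- next_subject + n_subj_per_class
      # subject-level split within class (stratified), shuffled
      n_tr <- round(split_fractions[[1]] * n_subj_per_class)
      n_va <- round(split_fractions[[2]] * n_subj_per_class)
      n_tr <- min(n_tr, n_subj_per_class)
      n_va <- min(n_va, n_subj_per_class - n_tr)
      sp <- rep(c("train", "val", "test"),
                c(n_tr, n_va, n_subj_per_class - n_tr - n_va))
      sp <- sp[sample.int(length(sp))]
      made <- 0L
      for (si in seq_along(subj_ids)) {
        for (j in seq_len(images_per_subject)) {
          if (made >= n_per_class) break
          made <- made + 1L
          cfg <- phantom_config(modality = modality, image_size = image_size,
                                grade = classes[ci], subject_id = subj_ids[si],
                                seed = sample.int(2^30, 1L))
          img <- generate_phantom(cfg)
          images[[length(images) + 1L]] <- img
          split <- c(split, sp[si])
          labels <- c(labels, ci)
          subjects <- c(subjects, subj_ids[si])
        }
      }
    }
  })
  structure(list(images = images, split = split, label = labels,
                 subject_id = subjects, modality = modality,
                 classes = classes, image_size = as.integer(image_size)),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> %s, %d images (%s), classes: %s\n",
              x$modality, length(x$images),
              paste(names(table(x$split)), table(x$split),
                    sep = "=", collapse = " "),
              paste(x$classes, collapse = "/")))
  invisible(x)
}

#' Balance training classes by oversampling
#'
#' Duplicates training entries of minority classes (cycling through the
#' originals) until every class matches the largest class. Validation and
#' test splits are untouched.
#'
#' @param dataset A `phantom_dataset`.
#' @return A `phantom_dataset` with a balanced training split.
#' @export
balance_by_oversampling <- function(dataset) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  tr <- which(dataset$split == "train")
  if (length(tr) == 0) return(dataset)
  tab <- table(dataset$label[tr])
  target <- max(tab)
  add <- integer(0)
  for (cl in names(tab)) {
    idx <- tr[dataset$label[tr] == as.integer(cl)]
    if (length(idx) < target) {
      extra <- rep(idx, length.out = target)[(length(idx) + 1L):target]
      add <- c(add, extra)
    }
  }
  if (length(add)) {
    dataset$images <- c(dataset$images, dataset$images[add])
    dataset$split <- c(dataset$split, dataset$split[add])
    dataset$label <- c(dataset$label, dataset$label[add])
    dataset$subject_id <- c(dataset$subject_id, dataset$subject_id[add])
  }
  dataset
}

#' Flatten a dataset split into a design matrix
#'
#' @param dataset A `phantom_dataset`.
#' @param split One of `"train"`, `"val"`, `"test"`, or `"all"`.
#' @return List with `X` (one flattened image per row, values in `[0,1]`),
#'   `y` (integer class labels), `grades`, `subject_id`.
#' @export
dataset_matrix <- function(dataset, split = "train") {
  idx <- if (identical(split, "all")) seq_along(dataset$images)
         else which(dataset$split == split)
  X <- do.call(rbind, lapply(dataset$images[idx],
                             function(im) as.vector(im$pixels)))
  list(X = X, y = dataset$label[idx],
       grades = vapply(dataset$images[idx], function(im) im$grade, ""),
       subject_id = dataset$subject_id[idx])
}

# --- lesion oracle -------------------------------------------------------

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so merge
# labels that touch diagonally.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  for (dy in c(-1L, 1L)) {
    a <- lab[seq_len(nr - 1L), seq_len(nc - 1L), drop = FALSE]
    b <- if (dy == 1L) lab[2:nr, 2:nc, drop = FALSE]
         else lab[2:nr, seq_len(nc - 1L), drop = FALSE]
    if (dy == -1L) a <- lab[seq_len(nr - 1L), 2:nc, drop = FALSE]
    touch <- which(a > 0 & b > 0 & a != b)
    for (i in touch) {
      ra <- find(a[i]); rb <- find(b[i])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  out <- lab
  out[lab > 0] <- match(roots[lab[lab > 0]], sort(unique(roots)))
  out
}

count_components <- function(mask, min_px) {
  if (!any(mask)) return(list(n = 0L, sizes = integer(0), lab = NULL))
  lab <- label8(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- sizes >= min_px
  list(n = sum(keep), sizes = sizes[keep], lab = lab)
}

#' Count lesions in an image by thresholded blob detection
#'
#' The detection thresholds (from [phantom_palette()]) are calibrated on the
#' phantom renderer so that, on generator output, the returned counts equal
#' the ground-truth `lesion_counts` exactly; on arbitrary images the oracle
#' counts connected components passing the same size and contrast rules.
#' Fundus: dark-red components in the green channel split by area into
#' microaneurysms and hemorrhages, plus bright-yellow exudate components.
#' OCT: bright sub-RPE drusen deposits, dark intraretinal cavities, and a
#' subretinal membrane below the RPE.
#'
#' @param pixels Fundus H x W x 3 array or OCT H x W matrix, values in `[0,1]`.
#' @param modality `"fundus"` or `"oct"`.
#' @return Named integer vector of lesion counts per type.
#' @export
lesion_oracle <- function(pixels, modality = c("fundus", "oct")) {
  modality <- match.arg(modality)
  pal <- phantom_palette()
  if (any(pixels < -1e-9) || any(pixels > 1 + 1e-9)) {
    stop("pixels must lie in [0,1]")
  }
  if (modality == "fundus") {
    if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
      stop("fundus oracle expects an H x W x 3 array")
    }
    g <- pixels[, , 2]; r <- pixels[, , 1]; b <- pixels[, , 3]
    dark <- g < pal$dark_green_thr & r > 0.15 & r < 0.5
    cc <- count_components(dark, pal$dark_min_px)
    ma <- sum(cc$sizes < pal$dark_area_split)
    hem <- sum(cc$sizes >= pal$dark_area_split)
    ex <- count_components(r > pal$exudate_thr[["r"]] &
                             g > pal$exudate_thr[["g"]] &
                             b < pal$exudate_thr[["b"]], pal$dark_min_px)$n
    c(microaneurysm = ma, hemorrhage = hem, exudate = ex)
  } else {
    if (!is.matrix(pixels)) {
      if (length(dim(pixels)) == 3 && dim(pixels)[3] == 1) pixels <- pixels[, , 1]
      else stop("oct oracle expects an H x W matrix")
    }
    n <- nrow(pixels)
    rpe_row <- apply(pixels, 2L, which.max)
    rpe_bot <- vapply(seq_len(ncol(pixels)), function(x) {
      w <- which(pixels[, x] > 0.6)
      if (length(w)) max(w) else n
    }, 1L)
    top_row <- vapply(seq_len(ncol(pixels)), function(x) {
      w <- which(pixels[, x] > 0.25)
      if (length(w)) min(w) else 1L
    }, 1L)
    rows <- matrix(seq_len(n), n, ncol(pixels))
    drus <- count_components(pixels > pal$oct_drusen_thr, 3L)$n
    cav_mask <- pixels < pal$oct_cavity_thr &
      rows > matrix(top_row + 1, n, ncol(pixels), byrow = TRUE) &
      rows < matrix(rpe_row - 1, n, ncol(pixels), byrow = TRUE)
    cav <- count_components(cav_mask, 3L)$n
    cnv_mask <- pixels > pal$oct_cnv_thr & pixels < 0.7 &
      rows > matrix(rpe_bot, n, ncol(pixels), byrow = TRUE)
    cnv <- count_components(cnv_mask, 4L)$n
    c(drusen = drus, cavity = cav, cnv = cnv)
  }
}
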