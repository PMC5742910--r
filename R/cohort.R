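#' Configuration for synthetic two-group cohorts
#'
#' Defaults reproduce the published study conditions: 25 ADHD subjects
#' (20 male / 5 female, ages 20-50, BEN 0.56 +/- 0.14) versus 19 controls
#' (8 male / 11 female, ages 18-46, BEN 0.64 +/- 0.11), two component images
#' per subject. The control group defaults to the n = 19 composition of the
#' realised analysis table (one recruited participant was excluded for lack
#' of meaningful activation); `follow_recruitment = TRUE` switches to the
#' recruitment composition (n = 20, 8 male / 12 female).
#'
#' @param n_adhd,n_control subjects per group.
#' @param ben_mean,ben_sd named numeric (`adhd`, `control`): target normalised
#'   entropy distribution per group, truncated to (0, 1).
#' @param age_mean,age_sd named numeric: age distribution (years) per group.
#' @param age_range list of length-2 numeric ranges per group.
#' @param gender list of named counts `c(male =, female =)` per group; must
#'   sum to the group sizes.
#' @param images_per_subject component images per subject (default 2).
#' @param map_config a [map_gen_config()] template for the generated images.
#' @param follow_recruitment use the recruitment-stage control composition
#'   (n = 20, 8/12) instead of the analysis-table composition (n = 19, 8/11).
#' @param seed cohort RNG seed.
#' @return an object of class `cohort_gen_config`.
#' @export
cohort_gen_config <- function(n_adhd = 25L,
                              n_control = 19L,
                              ben_mean = c(adhd = 0.56, control = 0.64),
                              ben_sd = c(adhd = 0.14, control = 0.11),
                              age_mean = c(adhd = 34.52, control = 29.32),
                              age_sd = c(adhd = 9.54, control = 10.02),
                              age_range = list(adhd = c(20, 50),
                                               control = c(18, 46)),
                              gender = list(adhd = c(male = 20L, female = 5L),
                                            control = c(male = 8L,
                                                        female = 11L)),
                              images_per_subject = 2L,
                              map_config = map_gen_config(),
                              follow_recruitment = FALSE,
                              seed = 100L) {
  if (isTRUE(follow_recruitment)) {
    if (missing(n_control)) n_control <- 20L
    if (missing(gender)) {
      gender$control <- c(male = 8L, female = 12L)
    }
  }
  n <- c(adhd = as.integer(n_adhd), control = as.integer(n_control))
  if (any(n < 0)) stop("configuration error: group sizes must be >= 0")
  for (grp in c("adhd", "control")) {
    if (sum(gender[[grp]]) != n[[grp]]) {
      stop("configuration error: gender counts for ", grp,
           " must sum to the group size (", n[[grp]], ")")
    }
    if (ben_mean[[grp]] <= 0 || ben_mean[[grp]] >= 1 ||
        ben_sd[[grp]] <= 0 || ben_sd[[grp]] >= 1) {
      stop("configuration error: target BEN means/SDs must lie in (0, 1)")
    }
  }
  stopifnot(inherits(map_config, "map_gen_config"))
  structure(list(n = n, ben_mean = ben_mean, ben_sd = ben_sd,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 gender = gender,
                 images_per_subject = as.integer(images_per_subject),
                 map_config = map_config,
                 follow_recruitment = isTRUE(follow_recruitment),
                 seed = as.integer(seed)),
            class = "cohort_gen_config")
}

# Exact inverse-CDF draw from a truncated normal.
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic two-group cohort
#'
#' Draws per-subject target BENs from truncated normals at the configured
#' group means/SDs, assigns ages and genders matching the configured margins,
#' and generates `images_per_subject` seeded component maps per subject whose
#' dispersion parameter is calibrated (via `curve`) so the realised image BEN
#' tracks the subject's target. Identical config + seed reproduces the cohort
#' byte for byte.
#'
#' @param config a [cohort_gen_config()].
#' @param dir optional output directory; when given, images are written as
#'   PNG under `dir/images/` and the subject table as `dir/subjects.csv`
#'   (header `subject_id,group,age,gender,image_1,image_2`), with the
#'   generator's target BENs in `dir/targets.csv`.
#' @param curve optional precomputed [calibration_curve()]; built from
#'   `config$map_config` when `NULL`.
#' @return an object of class `ben_cohort`: list with `subjects` (data frame:
#'   subject_id, group, age, gender, ben_target, image paths), `images`
#'   (named list of per-subject image lists), `curve`, and `config`.
#' @export
generate_cohort <- function(config = cohort_gen_config(), dir = NULL,
                            curve = NULL) {
  stopifnot(inherits(config, "cohort_gen_config"))
  if (is.null(curve)) {
    mc <- config$map_config
    mc$seed <- derive_seed(config$seed, 999983L)
    curve <- calibration_curve(mc)
  }
  n_total <- sum(config$n)
  groups <- rep(c("ADHD", "control"), times = config$n)
  key <- rep(c("adhd", "control"), times = config$n)
  subj_id <- sprintf("%s_%02d", tolower(groups),
                     unlist(lapply(config$n, seq_len), use.names = FALSE))
  draws <- with_seed(config$seed, {
    ben_target <- age <- numeric(n_total)
    gender <- character(n_total)
    for (grp in c("adhd", "control")) {
      sel <- key == grp
      ng <- sum(sel)
      if (ng == 0) next
      ben_target[sel] <- rtrunc_norm(ng, config$ben_mean[[grp]],
                                     config$ben_sd[[grp]], 0, 1)
      rng <- config$age_range[[grp]]
      age[sel] <- round(rtrunc_norm(ng, config$age_mean[[grp]],
                                    config$age_sd[[grp]], rng[1], rng[2]), 1)
      gcounts <- config$gender[[grp]]
      gender[sel] <- sample(rep(c("male", "female"), times = gcounts))
    }
    list(ben_target = ben_target, age = age, gender = gender)
  })
  # clamp targets into the calibratable range (documented behaviour)
  target <- pmin(pmax(draws$ben_target, min(curve$ben)), max(curve$ben))

  images <- vector("list", n_total)
  names(images) <- subj_id
  for (i in seq_len(n_total)) {
    h <- heterogeneity_for_ben(target[i], curve)
    imgs <- vector("list", config$images_per_subject)
    for (j in seq_len(config$images_per_subject)) {
      mc <- config$map_config
      mc$intensity_heterogeneity <- h
      mc$seed <- derive_seed(config$seed, i, j)
      imgs[[j]] <- generate_component_map(mc, subject_id = subj_id[i],
                                          component_index = j)
    }
    images[[i]] <- imgs
  }
  subjects <- data.frame(subject_id = subj_id, group = groups,
                         age = draws$age, gender = draws$gender,
                         ben_target = target,
                         image_1 = rep(NA_character_, n_total),
                         image_2 = rep(NA_character_, n_total),
                         stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    img_dir <- file.path(dir, "images")
    dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_total)) {
      for (j in seq_len(config$images_per_subject)) {
        p <- file.path(img_dir, sprintf("%s_%d.png", subj_id[i], j))
        write_component_image(images[[i]][[j]], p)
        if (j <= 2) subjects[[paste0("image_", j)]][i] <- p
      }
    }
    utils::write.csv(subjects[, c("subject_id", "group", "age", "gender",
                                  "image_1", "image_2")],
                     file.path(dir, "subjects.csv"), row.names = FALSE)
    utils::write.csv(subjects[, c("subject_id", "ben_target")],
                     file.path(dir, "targets.csv"), row.names = FALSE)
  }
  structure(list(subjects = subjects, images = images, curve = curve,
                 config = config),
            class = "ben_cohort")
}

#' @export
print.ben_cohort <- function(x, ...) {
  cat("<ben_cohort>", nrow(x$subjects), "subjects (",
      paste(names(table(x$subjects$group)), table(x$subjects$group),
            sep = " = ", collapse = ", "), ")\n")
  invisible(x)
}

#' Compute subject-level BEN for a whole cohort
#'
#' Runs the segmentation + entropy chain on every subject's images and
#' returns the subject table augmented with the realised BEN (and exclusion
#' flags for subjects without retained pixels).
#'
#' @param cohort a [generate_cohort()] result.
#' @param profiles colour profiles.
#' @return data frame: the cohort's subject table plus columns `ben` and
#'   `excluded`.
#' @export
analyze_cohort <- function(cohort, profiles = default_color_profiles()) {
  stopifnot(inherits(cohort, "ben_cohort"))
  subs <- cohort$subjects
  res <- lapply(seq_len(nrow(subs)), function(i) {
    subject_ben(cohort$images[[subs$subject_id[i]]],
                subject_id = subs$subject_id[i], profiles = profiles,
                images_per_subject = cohort$config$images_per_subject)
  })
  subs$ben <- vapply(res, `[[`, numeric(1), "ben")
  subs$excluded <- vapply(res, `[[`, logical(1), "excluded")
  subs
}
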