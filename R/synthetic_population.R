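# Unit direction in the zero-sum (simplex) plane along which skink dorsal
# chromaticity is offset from its background: toward red-brown.
.chrom_dir <- c(2, -1, -1) / sqrt(6)

# Orthonormal companion, for rotating the offset by seasonal hue shifts.
.chrom_dir_perp <- c(0, 1, -1) / sqrt(2)

#' Parameters for a synthetic skink population
#'
#' Encodes the statistical structure the analysis assumes, with every effect an
#' explicit, switch-offable parameter: background brightness declines steeply
#' with vegetation cover while dorsal brightness tracks it more weakly (so the
#' animal is darker than its background on bare sand and lighter under dense
#' cover); the skink-versus-background chromaticity offset has magnitude linear
#' in cover (the generating slope that regression should recover); ventral
#' saturation is elevated in adults and further in males; dorsal hue rotates
#' with season. Colors are built from brightness and simplex proportions as
#' \code{rgb = 3 V p}. Observed colors add Gaussian measurement noise to the
#' true colors. The paper-scale default is 352 individuals over survey years
#' 2006–2008.
#'
#' @param n number of individuals (default 352).
#' @param year_weights sampling weights for survey years 2006/2007/2008.
#' @param season_weights weights over seasons \code{nb, bm, bb}.
#' @param adult_prob probability an individual is adult.
#' @param male_prob probability an adult is male (juvenile sex recorded too).
#' @param bg_v0,bg_v_slope,bg_v_sd background brightness intercept, slope per
#'   percent cover (negative), and residual sd.
#' @param dorsal_v0,dorsal_v_slope,dorsal_v_sd same for dorsal brightness
#'   (slope negative, smaller magnitude).
#' @param chrom_offset0,chrom_offset_slope,chrom_offset_sd intercept, slope
#'   per percent cover, and sd of the skink-background chromaticity offset
#'   magnitude: the generating slope of chromatic contrast on cover.
#' @param bg_mix fraction of the sand-to-vegetation proportion shift realized
#'   at 100\% cover; \code{bg_mix_sd} its per-individual noise.
#' @param sand_rgb,veg_rgb substrate reflectances (proportions taken from
#'   them).
#' @param ventral_rgb,ventral_tail_rgb baseline ventral reflectances.
#' @param ventral_v0,ventral_v_sd,tail_v0,tail_v_sd ventral brightnesses.
#' @param adult_sat_gain,male_sat_gain multiplicative ventral chroma gains for
#'   adults and (additionally) adult males; \code{sat_sd} the chroma noise sd.
#'   The total chroma factor is capped at 1.5 so colors stay inside the
#'   camera's representable range.
#' @param year_v_sd,year_mag_sd between-year (random-intercept) standard
#'   deviations on brightness and on the chromaticity-offset magnitude;
#'   year-to-year environmental variation, shared by all individuals of a
#'   survey year.
#' @param season_hue_offset named radians by which the dorsal chromaticity
#'   offset direction rotates per season.
#' @param pattern_base_weights population-level weights of
#'   \code{plain, midplain, spot, midspot}.
#' @param pattern_cover_beta per-type log-weight tilt across cover (complex
#'   types more frequent under high cover).
#' @param meas_sd per-channel Gaussian measurement noise on observed colors.
#' @param svl_adult_mean,svl_adult_sd,svl_juv_mean,svl_juv_sd SVL (mm).
#' @param mass_a,mass_b,mass_sd mass-SVL allometry \code{mass = a * SVL^b *
#'   exp(noise)} (g, mm).
#' @param seed top-level population seed.
#' @return list of class \code{population_params}.
#' @export
population_params <- function(n = 352,
                              year_weights = c("2006" = 19, "2007" = 271, "2008" = 62),
                              season_weights = c(nb = 0.4, bm = 0.3, bb = 0.3),
                              adult_prob = 0.7, male_prob = 0.5,
                              bg_v0 = 0.42, bg_v_slope = -0.0022, bg_v_sd = 0.015,
                              dorsal_v0 = 0.40, dorsal_v_slope = -0.0016,
                              dorsal_v_sd = 0.02,
                              chrom_offset0 = 0.05, chrom_offset_slope = 8e-4,
                              chrom_offset_sd = 0.012,
                              bg_mix = 0.9, bg_mix_sd = 0.03,
                              sand_rgb = c(0.55, 0.50, 0.42),
                              veg_rgb = c(0.16, 0.24, 0.10),
                              ventral_rgb = c(0.48, 0.30, 0.16),
                              ventral_tail_rgb = c(0.50, 0.27, 0.15),
                              ventral_v0 = 0.40, ventral_v_sd = 0.025,
                              tail_v0 = 0.40, tail_v_sd = 0.025,
                              adult_sat_gain = 0.35, male_sat_gain = 0.15,
                              sat_sd = 0.08,
                              year_v_sd = 0.01, year_mag_sd = 0.006,
                              season_hue_offset = c(nb = 0.18, bm = 0.05, bb = -0.12),
                              pattern_base_weights = c(plain = 0.06, midplain = 0.19,
                                                       spot = 0.09, midspot = 0.66),
                              pattern_cover_beta = c(plain = -1.2, midplain = -0.4,
                                                     spot = -0.2, midspot = 0.35),
                              meas_sd = 0.004,
                              svl_adult_mean = 60, svl_adult_sd = 5,
                              svl_juv_mean = 38, svl_juv_sd = 4,
                              mass_a = 1.85e-5, mass_b = 3, mass_sd = 0.1,
                              seed = 1L) {
  check_that(n >= 0, "n must be >= 0")
  check_that(all(season_weights >= 0) && sum(season_weights) > 0,
             "season_weights must be non-negative and sum > 0")
  structure(as.list(environment()), class = "population_params")
}

#' Null-population parameters
#'
#' The generator with every effect switched off: zero cover slopes, zero
#' age/sex saturation gains, zero seasonal hue offsets, flat pattern-by-cover
#' structure, and the ventral-tail region drawn from the same distribution as
#' the dorsal region. Under these parameters any region/age/pattern comparison
#' is exchangeable, which is what the type-I-error checks need.
#'
#' @param n number of individuals.
#' @param seed population seed.
#' @return a [population_params()] object.
#' @export
null_population_params <- function(n = 40, seed = 1L) {
  p <- population_params(
    n = n, seed = seed,
    bg_v_slope = 0, dorsal_v_slope = 0,
    chrom_offset_slope = 0,
    adult_sat_gain = 0, male_sat_gain = 0,
    season_hue_offset = c(nb = 0, bm = 0, bb = 0),
    pattern_cover_beta = c(plain = 0, midplain = 0, spot = 0, midspot = 0),
    bg_mix = 0
  )
  # make regions exchangeable: tail behaves exactly like the dorsal region
  p$null_regions <- TRUE
  p
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# rgb triple from brightness V and simplex proportions p (rgb = 3 V p)
rgb_from_vp <- function(V, p) 3 * V * p

proportions_of <- function(rgb) rgb / sum(rgb)

#' Generate a synthetic population table
#'
#' Draws \code{n} individual records with the mean structure described in
#' [population_params()], then appends all derived columns (chromaticity,
#' saturation, hue, contrasts, SMI) with [augment_records()]. Fully
#' reproducible from the seed.
#'
#' @param p a [population_params()].
#' @return a tibble with one row per individual: identifiers and metadata,
#'   true and observed per-region colors, pattern descriptors, and derived
#'   color metrics.
#' @export
generate_population <- function(p) {
  check_that(inherits(p, "population_params"), "p must be population_params")
  n <- p$n
  empty <- augment_records(new_records(0))
  if (n == 0) return(empty)

  with_seed(derive_seed(p$seed, "population"), {
    yr_levels <- names(p$year_weights)
    year_v_eff <- stats::setNames(stats::rnorm(length(yr_levels), 0, p$year_v_sd),
                                  yr_levels)
    year_mag_eff <- stats::setNames(stats::rnorm(length(yr_levels), 0, p$year_mag_sd),
                                    yr_levels)
    year <- sample(yr_levels, n, replace = TRUE,
                   prob = p$year_weights / sum(p$year_weights))
    season <- sample(names(p$season_weights), n, replace = TRUE,
                     prob = p$season_weights / sum(p$season_weights))
    age <- ifelse(stats::runif(n) < p$adult_prob, "adult", "juvenile")
    sex <- ifelse(stats::runif(n) < p$male_prob, "male", "female")
    cover <- sample(seq(0, 100, by = 5), n, replace = TRUE)

    svl <- ifelse(age == "adult",
                  clamp(stats::rnorm(n, p$svl_adult_mean, p$svl_adult_sd), 48, 72),
                  clamp(stats::rnorm(n, p$svl_juv_mean, p$svl_juv_sd), 28, 48))
    mass <- p$mass_a * svl^p$mass_b * exp(stats::rnorm(n, 0, p$mass_sd))

    # pattern type: weights tilted along the cover gradient
    lvl <- pattern_levels()
    wbase <- p$pattern_base_weights[lvl]
    beta <- p$pattern_cover_beta[lvl]
    pattern <- character(n)
    for (i in seq_len(n)) {
      wt <- wbase * exp(beta * (cover[i] - 50) / 50)
      pattern[i] <- sample(lvl, 1, prob = wt / sum(wt))
    }
    speckle_fraction <- ifelse(pattern %in% c("spot", "midspot"),
                               stats::runif(n, 0.15, 0.35),
                               stats::runif(n, 0, 0.05))
    midline_coverage <- ifelse(pattern %in% c("midplain", "midspot"),
                               stats::runif(n, 0.60, 0.95),
                               stats::runif(n, 0, 0.40))

    # background color: proportions slide from sand toward vegetation,
    # brightness declines with cover
    p_sand <- proportions_of(p$sand_rgb)
    p_veg <- proportions_of(p$veg_rgb)
    wmix <- clamp(p$bg_mix * cover / 100 + stats::rnorm(n, 0, p$bg_mix_sd), 0, 1)
    bg_V <- clamp(p$bg_v0 + p$bg_v_slope * cover + year_v_eff[year] +
                    stats::rnorm(n, 0, p$bg_v_sd), 0.05, 0.9)
    bg_prop <- outer(1 - wmix, p_sand) + outer(wmix, p_veg)

    # dorsal: brightness tracks cover weakly; chromaticity sits at the
    # background's, displaced along a season-rotated direction by a magnitude
    # linear in cover (the generating chromatic-contrast structure)
    dors_V <- clamp(p$dorsal_v0 + p$dorsal_v_slope * cover + year_v_eff[year] +
                      stats::rnorm(n, 0, p$dorsal_v_sd), 0.05, 0.9)
    mag <- p$chrom_offset0 + p$chrom_offset_slope * cover + year_mag_eff[year] +
      stats::rnorm(n, 0, p$chrom_offset_sd)
    theta <- p$season_hue_offset[season]
    dir_mat <- outer(cos(theta), .chrom_dir) + outer(sin(theta), .chrom_dir_perp)
    dors_prop <- bg_prop + dir_mat * mag
    dors_prop <- pmax(dors_prop, 1e-4)
    dors_prop <- dors_prop / rowSums(dors_prop)

    # ventral regions: fixed baseline proportions with age/sex chroma gains
    sat_factor <- 1 + p$adult_sat_gain * (age == "adult") +
      p$male_sat_gain * (age == "adult" & sex == "male") +
      stats::rnorm(n, 0, p$sat_sd)
    sat_factor <- clamp(sat_factor, 0.05, 1.5)
    scale_chroma <- function(base_rgb, fac) {
      pb <- proportions_of(base_rgb)
      pr <- outer(rep(1, length(fac)), rep(1 / 3, 3)) +
        outer(fac, pb - 1 / 3)
      pr <- pmax(pr, 1e-4)
      pr / rowSums(pr)
    }
    vent_prop <- scale_chroma(p$ventral_rgb, sat_factor)
    tail_prop <- scale_chroma(p$ventral_tail_rgb, sat_factor)
    vent_V <- clamp(stats::rnorm(n, p$ventral_v0, p$ventral_v_sd), 0.05, 0.9)
    tail_V <- clamp(stats::rnorm(n, p$tail_v0, p$tail_v_sd), 0.05, 0.9)

    if (isTRUE(p$null_regions)) {
      # exchangeable-with-dorsal tail draws for type-I-error checks; the
      # year effects are shared with the dorsal region so paired differences
      # stay symmetric about zero
      tail_V <- clamp(p$dorsal_v0 + year_v_eff[year] +
                        stats::rnorm(n, 0, p$dorsal_v_sd), 0.05, 0.9)
      mag2 <- p$chrom_offset0 + year_mag_eff[year] +
        stats::rnorm(n, 0, p$chrom_offset_sd)
      tail_prop <- bg_prop + dir_mat * mag2
      tail_prop <- pmax(tail_prop, 1e-4)
      tail_prop <- tail_prop / rowSums(tail_prop)
    }

    true_cols <- list(
      dorsal = 3 * dors_V * dors_prop,
      ventral = 3 * vent_V * vent_prop,
      ventral_tail = 3 * tail_V * tail_prop,
      background = 3 * bg_V * bg_prop
    )
    # keep every channel inside the camera's representable range (max default
    # gain 1.2 against an 8-bit sensor), as field exposure settings would
    true_cols <- lapply(true_cols, function(m) pmin(m, 0.82))
    obs_cols <- lapply(true_cols, function(m)
      pmax(m + matrix(stats::rnorm(length(m), 0, p$meas_sd), nrow(m)), 1e-6))

    tbl <- tibble::tibble(
      id = sprintf("sk%04d", seq_len(n)),
      year = year, season = season, age = age, sex = sex,
      svl = svl, mass = mass, vegetation_cover = cover,
      pattern = pattern, speckle_fraction = speckle_fraction,
      midline_coverage = midline_coverage
    )
    for (reg in names(true_cols)) {
      for (ci in 1:3) {
        ch <- c("R", "G", "B")[ci]
        tbl[[paste0("true_", reg, "_", ch)]] <- true_cols[[reg]][, ci]
        tbl[[paste0(reg, "_", ch)]] <- obs_cols[[reg]][, ci]
      }
    }
    augment_records(tbl)
  })
}

# Zero-row record skeleton with the raw generator columns.
new_records <- function(n) {
  tbl <- tibble::tibble(
    id = character(n), year = character(n), season = character(n),
    age = character(n), sex = character(n), svl = numeric(n),
    mass = numeric(n), vegetation_cover = numeric(n), pattern = character(n),
    speckle_fraction = numeric(n), midline_coverage = numeric(n)
  )
  for (reg in c("dorsal", "ventral", "ventral_tail", "background")) {
    for (ch in c("R", "G", "B")) {
      tbl[[paste0("true_", reg, "_", ch)]] <- numeric(n)
      tbl[[paste0(reg, "_", ch)]] <- numeric(n)
    }
  }
  tbl
}

#' Append derived color metrics to a record table
#'
#' For each region (dorsal, ventral, ventral tail, background) with observed
#' \code{<region>_R/G/B} columns, appends brightness \code{V}, chromaticity
#' \code{x, y}, saturation \code{S}, hue \code{H} (NA when achromatic), and
#' for body regions the achromatic, absolute-achromatic, and chromatic
#' contrasts against the background. Appends the scaled mass index \code{smi}
#' when at least three complete mass/SVL pairs are present. Rows with missing
#' region channels get NA metrics rather than being dropped.
#'
#' @param tbl record table (tibble or data frame).
#' @return tibble with derived columns appended.
#' @export
augment_records <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  regions <- c("dorsal", "ventral", "ventral_tail", "background")
  for (reg in regions) {
    cols <- paste0(reg, "_", c("R", "G", "B"))
    if (!all(cols %in% names(tbl))) next
    m <- as.matrix(tbl[cols])
    s <- rowSums(m)
    tbl[[paste0(reg, "_V")]] <- s / 3
    x <- (m[, 1] - m[, 2]) / s
    y <- (m[, 2] - m[, 3]) / s
    tbl[[paste0(reg, "_x")]] <- x
    tbl[[paste0(reg, "_y")]] <- y
    tbl[[paste0(reg, "_S")]] <- sqrt(x^2 + y^2)
    tbl[[paste0(reg, "_H")]] <- ifelse(x == 0 & y == 0, NA_real_, atan2(y, x))
  }
  bg_cols <- paste0("background_", c("R", "G", "B"))
  if (all(bg_cols %in% names(tbl))) {
    bg <- as.matrix(tbl[bg_cols])
    for (reg in c("dorsal", "ventral", "ventral_tail")) {
      cols <- paste0(reg, "_", c("R", "G", "B"))
      if (!all(cols %in% names(tbl))) next
      m <- as.matrix(tbl[cols])
      ssum <- rowSums(m); bsum <- rowSums(bg)
      a <- (ssum - bsum) / (ssum + bsum)
      tbl[[paste0(reg, "_achromatic")]] <- a
      tbl[[paste0(reg, "_abs_achromatic")]] <- abs(a)
      dp <- m / ssum - bg / bsum
      tbl[[paste0(reg, "_chromatic")]] <- sqrt(rowSums(dp^2))
    }
  }
  if (all(c("mass", "svl") %in% names(tbl))) {
    ok <- stats::complete.cases(tbl$mass, tbl$svl)
    tbl$smi <- NA_real_
    if (sum(ok) >= 3 && stats::var(tbl$svl[ok]) > 0) {
      smi <- scaled_mass_index(tbl$mass[ok], tbl$svl[ok])
      tbl$smi[ok] <- as.numeric(smi)
    }
  }
  tbl
}

#' Render the scene implied by one individual record
#'
#' Copies the record's true colors, vegetation cover, and pattern descriptors
#' into [scene_params()] and renders, painting the two background patches flat
#' with the record's true background color. This is the link between the
#' tabular and image pipelines: extracting the rendered scene must recover the
#' record's colors and contrasts up to camera noise.
#'
#' @param record one-row record (as from [generate_population()]).
#' @param seed scene seed; by default derived from the record id.
#' @param ... overrides passed to [scene_params()] (e.g. camera settings).
#' @return a \code{scene_bundle}.
#' @export
scene_from_record <- function(record, seed = NULL, ...) {
  check_that(nrow(record) == 1, "record must be a single row")
  need <- c(paste0("true_", rep(c("dorsal", "ventral", "ventral_tail",
                                  "background"), each = 3), "_",
                   c("R", "G", "B")), "vegetation_cover")
  check_that(all(need %in% names(record)), "record lacks true color columns")
  if (anyNA(record[need])) stop("missing true colors in record", call. = FALSE)
  if (is.null(seed)) seed <- derive_seed(1L, paste0("scene-", record$id))
  tr <- function(reg) as.numeric(record[paste0("true_", reg, "_", c("R", "G", "B"))])
  p <- scene_params(
    cover = record$vegetation_cover / 100,
    dorsal_rgb = tr("dorsal"), ventral_rgb = tr("ventral"),
    ventral_tail_rgb = tr("ventral_tail"), background_rgb = tr("background"),
    speckle_fraction = record$speckle_fraction,
    midline_fraction = record$midline_coverage,
    seed = seed, ...
  )
  render_scene(p)
}
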