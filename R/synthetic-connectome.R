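# Synthetic fiber-count connectomes.  The study's raw diffusion data are not
# deposited, so the pipeline is exercised on generated per-subject
# connectivity matrices with the statistical structure the analysis assumes:
# a fixed ROI set embedded in space, modular organization, distance-dependent
# connection probability, heavy-tailed (lognormal) fiber counts, and
# subject-level multiplicative noise around a shared group backbone.

#' Connectome generation profile
#'
#' Parameters of the synthetic fiber-count generator.  Defaults describe a
#' 358-ROI cortex (the DICCCOL landmark count) organized into modules, and
#' are chosen so that thresholding at the default pipeline threshold yields
#' sparse (~5% density), clustered, short-path networks.
#'
#' @param n_rois Number of ROIs / network nodes (default 358).
#' @param n_modules Number of spatial modules (default 6).
#' @param intra_module_density Base connection probability within a module.
#' @param inter_module_density Base connection probability between modules;
#'   must not exceed `intra_module_density`.
#' @param weight_scale Median fiber count of a realized connection (the
#'   lognormal scale).
#' @param distance_decay Exponential decay rate of connection probability
#'   with Euclidean ROI distance (unit-cube units).
#' @param noise_sd Standard deviation (log scale) of per-subject
#'   multiplicative noise on the group backbone counts.
#' @param seed Integer RNG seed.
#' @return A list of class `connectome_profile`.
#' @export
connectome_profile <- function(n_rois = 358L,
                               n_modules = 6L,
                               intra_module_density = 0.55,
                               inter_module_density = 0.06,
                               weight_scale = 30,
                               distance_decay = 3,
                               noise_sd = 0.25,
                               seed = 1L) {
  p <- structure(
    list(
      n_rois = as.integer(n_rois),
      n_modules = as.integer(n_modules),
      intra_module_density = intra_module_density,
      inter_module_density = inter_module_density,
      weight_scale = weight_scale,
      distance_decay = distance_decay,
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "connectome_profile"
  )
  validate_profile(p)
}

validate_profile <- function(p) {
  if (!is_count(p$n_rois, min = 2L)) {
    abort("invalid profile: n_rois must be an integer >= 2")
  }
  if (!is_count(p$n_modules)) {
    abort("invalid profile: n_modules must be a positive integer")
  }
  if (!is_prob(p$intra_module_density) || !is_prob(p$inter_module_density)) {
    abort("invalid profile: densities must lie in [0, 1]")
  }
  if (p$inter_module_density > p$intra_module_density) {
    abort("invalid profile: inter_module_density must not exceed intra_module_density")
  }
  if (p$weight_scale <= 0 || p$distance_decay < 0 || p$noise_sd < 0) {
    abort("invalid profile: weight_scale > 0, distance_decay >= 0, noise_sd >= 0 required")
  }
  invisible(p)
}

#' Sample ROI positions and module assignments
#'
#' Places `n_rois` points in the unit cube: module centers are uniform, ROIs
#' scatter around their module's center with a Gaussian jitter (clamped to
#' the cube).  Deterministic given the profile seed.
#'
#' @param profile A [connectome_profile()].
#' @return A tibble with `roi` (0-based id), `module`, and coordinates
#'   `x`, `y`, `z`.
#' @export
sample_roi_positions <- function(profile) {
  validate_profile(profile)
  n <- profile$n_rois
  k <- profile$n_modules
  with_seed(derive_seed(profile$seed, 1L), {
    centers <- matrix(runif(k * 3, 0.15, 0.85), ncol = 3)
    module <- sample(rep_len(seq_len(k), n))
    jitter <- matrix(rnorm(n * 3, sd = 0.08), ncol = 3)
    pos <- pmin(pmax(centers[module, , drop = FALSE] + jitter, 0), 1)
    tibble::tibble(
      roi = seq_len(n) - 1L,
      module = module,
      x = pos[, 1], y = pos[, 2], z = pos[, 3]
    )
  })
}

new_connectivity_matrix <- function(counts, subject_id, group) {
  stopifnot(isTRUE(all.equal(counts, t(counts))), all(counts >= 0),
            all(diag(counts) == 0))
  structure(
    list(counts = counts, subject_id = subject_id, group = group),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf(
    "Connectivity matrix: %d ROIs, subject '%s' (%s), %d connected pairs\n",
    nrow(x$counts), x$subject_id, x$group,
    sum(x$counts[upper.tri(x$counts)] > 0)
  ))
  invisible(x)
}

# Group-level backbone: symmetric integer fiber counts shared by all
# subjects of a group before subject noise.
connectome_backbone <- function(profile, seed) {
  pos <- sample_roi_positions(profile)
  n <- profile$n_rois
  xyz <- as.matrix(pos[, c("x", "y", "z")])
  D <- as.matrix(stats::dist(xyz))
  same_mod <- outer(pos$module, pos$module, "==")
  base <- ifelse(same_mod, profile$intra_module_density,
                 profile$inter_module_density)
  P <- base * exp(-profile$distance_decay * D)
  with_seed(seed, {
    ut <- upper.tri(P)
    exists <- ut & matrix(runif(n * n), n, n) < P
    counts <- matrix(0, n, n)
    m <- sum(exists)
    if (m > 0) {
      # heavy-tailed positive fiber counts, at least 1
      w <- pmax(1, round(rlnorm(m, meanlog = log(profile$weight_scale),
                                sdlog = 1)))
      counts[exists] <- w
    }
    counts <- counts + t(counts)
    storage.mode(counts) <- "integer"
    counts
  })
}

#' Generate one synthetic connectivity matrix
#'
#' Draws a symmetric non-negative integer fiber-count matrix with zero
#' diagonal.  Expected counts increase with shared module membership and
#' decrease exponentially with ROI distance; realized counts are
#' lognormal-rounded.  Deterministic given the profile (including its seed).
#'
#' @param profile A [connectome_profile()].
#' @param subject_id,group Metadata attached to the matrix.
#' @return A `connectivity_matrix` object (fields `counts`, `subject_id`,
#'   `group`).
#' @export
generate_connectome <- function(profile, subject_id = "s1", group = "adult") {
  validate_profile(profile)
  counts <- connectome_backbone(profile, derive_seed(profile$seed, 2L))
  new_connectivity_matrix(counts, subject_id, group)
}

#' Generate a subject group of connectivity matrices
#'
#' All subjects share the profile's structural backbone; each receives
#' independent multiplicative lognormal noise (`noise_sd` on the log scale)
#' on the backbone counts.  `noise_sd = 0` makes all subjects identical.
#' Deterministic given profile seed and group label.
#'
#' @param profile A [connectome_profile()].
#' @param n_subjects Number of subjects (>= 1).
#' @param group Group label (e.g. `"adolescent"`, `"adult"`, `"elderly"`).
#' @return A list of `connectivity_matrix` objects.
#' @export
#' @examples
#' prof <- connectome_profile(n_rois = 60, seed = 7)
#' mats <- generate_group(prof, n_subjects = 3, group = "adolescent")
generate_group <- function(profile, n_subjects, group = "adult") {
  validate_profile(profile)
  if (!is_count(n_subjects)) {
    abort("n_subjects must be a positive integer")
  }
  backbone <- connectome_backbone(profile, derive_seed(profile$seed, 2L))
  n <- profile$n_rois
  group_salt <- sum(utf8ToInt(group))
  lapply(seq_len(n_subjects), function(s) {
    counts <- backbone
    if (profile$noise_sd > 0) {
      counts <- with_seed(derive_seed(profile$seed, 1000L + group_salt * 131L + s), {
        eps <- matrix(0, n, n)
        eps[upper.tri(eps)] <- rnorm(n * (n - 1) / 2, sd = profile$noise_sd)
        eps <- eps + t(eps)
        out <- round(backbone * exp(eps))
        storage.mode(out) <- "integer"
        out
      })
    }
    new_connectivity_matrix(counts, sprintf("%s_%02d", group, s), group)
  })
}
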