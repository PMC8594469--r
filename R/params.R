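#' Parameters of the particle motion model
#'
#' Bundles the physical parameters of the two-state motion model used by the
#' simulator: Brownian diffusion (diffusion coefficient `D`, µm²/s) and
#' persistent directed runs (speed µm/s with small per-step angular jitter).
#' Acquisition is described by the frame interval (s) and the number of
#' frames; apparent positions carry Gaussian localization noise (µm).
#'
#' Defaults describe fast kinesin-driven mRNP transport imaged by spinning
#' disk confocal at 6.66 frames per second: `directed_speed = 2.6` µm/s,
#' a 5% directed subpopulation, and `D = 0.1` µm²/s for the diffusive pool.
#'
#' @param diffusion_coefficient Diffusion coefficient, µm²/s (>= 0).
#' @param directed_speed Run speed of directed particles, µm/s (>= 0).
#' @param directed_fraction Proportion of directed particles in `[0, 1]`.
#' @param direction_jitter Per-step angular jitter of directed runs,
#'   radians/step (>= 0).
#' @param frame_interval Time between frames, s (> 0).
#' @param n_frames Number of frames per track (>= 2).
#' @param localization_noise Std. dev. of apparent-position noise, µm (>= 0).
#' @return An object of class `motion_params`.
#' @export
motion_params <- function(diffusion_coefficient = 0.1,
                          directed_speed = 2.6,
                          directed_fraction = 0.05,
                          direction_jitter = 0.1,
                          frame_interval = 1 / 6.66,
                          n_frames = 100L,
                          localization_noise = 0.03) {
  stopifnot(is.numeric(diffusion_coefficient), length(diffusion_coefficient) == 1)
  if (diffusion_coefficient < 0) stop("diffusion_coefficient must be >= 0")
  if (directed_speed < 0) stop("directed_speed must be >= 0")
  if (directed_fraction < 0 || directed_fraction > 1) {
    stop("directed_fraction must lie in [0, 1]")
  }
  if (direction_jitter < 0) stop("direction_jitter must be >= 0")
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be > 0")
  }
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stop("n_frames must be >= 2")
  if (localization_noise < 0) stop("localization_noise must be >= 0")
  structure(
    list(
      diffusion_coefficient = diffusion_coefficient,
      directed_speed = directed_speed,
      directed_fraction = directed_fraction,
      direction_jitter = direction_jitter,
      frame_interval = frame_interval,
      n_frames = n_frames,
      localization_noise = localization_noise
    ),
    class = "motion_params"
  )
}

#' Cytoskeletal drug perturbations emulated by the simulator
#'
#' `nocodazole` depolymerizes microtubules and abolishes the directed
#' population; `cytochalasinD` (actin) and `dmso` (vehicle) leave directed
#' motion unchanged; `none` is the untreated condition.
#'
#' @param kind One of `"none"`, `"nocodazole"`, `"cytochalasinD"`, `"dmso"`.
#' @return An object of class `perturbation`.
#' @export
perturbation <- function(kind = c("none", "nocodazole", "cytochalasinD", "dmso")) {
  kind <- match.arg(kind)
  structure(list(kind = kind), class = "perturbation")
}

#' Parameters of the synthetic image renderer
#'
#' @param psf_sigma Gaussian point-spread-function sigma, µm (> 0).
#' @param single_molecule_mean Mean integrated intensity of one molecule, a.u.
#' @param single_molecule_sd Std. dev. of single-molecule intensity, a.u.
#' @param cluster_multiplicity Number of molecules per rendered cluster (>= 2).
#' @param background_level Constant background offset, a.u.
#' @param noise_sd Std. dev. of additive Gaussian camera noise, a.u.
#' @return An object of class `render_params`.
#' @export
render_params <- function(psf_sigma = 0.17,
                          single_molecule_mean = 1000,
                          single_molecule_sd = 150,
                          cluster_multiplicity = 6L,
                          background_level = 100,
                          noise_sd = 0) {
  if (psf_sigma <= 0) stop("psf_sigma must be > 0")
  if (single_molecule_mean <= 0) stop("single_molecule_mean must be > 0")
  if (single_molecule_sd < 0) stop("single_molecule_sd must be >= 0")
  cluster_multiplicity <- as.integer(cluster_multiplicity)
  if (cluster_multiplicity < 2L) stop("cluster_multiplicity must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(
    list(
      psf_sigma = psf_sigma,
      single_molecule_mean = single_molecule_mean,
      single_molecule_sd = single_molecule_sd,
      cluster_multiplicity = cluster_multiplicity,
      background_level = background_level,
      noise_sd = noise_sd
    ),
    class = "render_params"
  )
}

#' Spot-detection parameters
#'
#' @param log_sigma Scale of the Laplacian-of-Gaussian filter, µm (> 0).
#'   Matched to the PSF sigma of the data for best response.
#' @param threshold Detection threshold on the filtered image, a.u., or `NULL`
#'   to use a per-image automatic threshold: mean + 5 sd of the filtered
#'   background, estimated robustly as median + 5 MAD so bright spots do not
#'   inflate the cut.
#' @param min_separation Minimum distance between accepted detections, µm
#'   (>= 0).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(log_sigma = 0.17,
                             threshold = NULL,
                             min_separation = 2 * log_sigma) {
  if (log_sigma <= 0) stop("log_sigma must be > 0")
  if (!is.null(threshold) && (!is.numeric(threshold) || length(threshold) != 1)) {
    stop("threshold must be a single number or NULL")
  }
  if (min_separation < 0) stop("min_separation must be >= 0")
  structure(
    list(
      log_sigma = log_sigma,
      threshold = threshold,
      min_separation = min_separation
    ),
    class = "detection_params"
  )
}

#' Track-classification thresholds
#'
#' Tracks are retained when their duration strictly exceeds `min_duration`
#' and classified as long/directed when both net displacement and linearity
#' of forward progression strictly exceed their thresholds.
#'
#' @param min_duration Minimum track duration, s (default 2.5).
#' @param min_displacement Minimum net displacement, µm (default 4).
#' @param min_linearity Minimum linearity of forward progression (default 0.7).
#' @return An object of class `classifier_thresholds`.
#' @export
classifier_thresholds <- function(min_duration = 2.5,
                                  min_displacement = 4,
                                  min_linearity = 0.7) {
  if (min_duration <= 0) stop("min_duration must be > 0")
  if (min_displacement <= 0) stop("min_displacement must be > 0")
  if (min_linearity <= 0 || min_linearity > 1) {
    stop("min_linearity must be in (0, 1]")
  }
  structure(
    list(
      min_duration = min_duration,
      min_displacement = min_displacement,
      min_linearity = min_linearity
    ),
    class = "classifier_thresholds"
  )
}

# Evaluate `code` under a fixed RNG state and restore the caller's stream.
# Every stochastic operation takes an explicit seed and uses one stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
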