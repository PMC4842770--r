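# ---- synthetic-data generators ---------------------------------------------
# Everything needed to exercise the full pipeline without any download: a
# brain-like closed mesh, strip montages, phase-coupled signal pairs with a
# known population PLV, and ERP-structured multichannel recordings.

icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(1 + t^2)
  f <- rbind(c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
             c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
             c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
             c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1))
  list(vertices = v, faces = f + 1L)
}

icosphere <- function(subdivisions = 3L) {
  m <- icosahedron()
  v <- m$vertices
  f <- m$faces
  for (s in seq_len(subdivisions)) {
    midcache <- new.env(parent = emptyenv())
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- midcache[[key]]
      if (!is.null(hit)) return(hit)
      p <- v[a, ] + v[b, ]
      p <- p / sqrt(sum(p * p))
      v <<- rbind(v, p)
      idx <- nrow(v)
      midcache[[key]] <- idx
      idx
    }
    nf <- matrix(0L, 0L, 3L)
    newf <- vector("list", nrow(f))
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      newf[[i]] <- rbind(c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc),
                         c(ab, bc, ca))
    }
    f <- do.call(rbind, newf)
  }
  list(vertices = v, faces = f)
}

#' Synthetic brain-like surface mesh
#'
#' A subdivided icosahedron (icosphere, 10 * 4^s + 2 vertices) scaled
#' anisotropically to typical adult brain extents (default 140 x 170 x
#' 120 mm in RAS: width x length x height). The surface is closed and
#' validated. It has no anatomical folding: none of the algorithms here
#' depend on anatomy, only on having a closed star-shaped surface.
#'
#' @param subdivisions icosphere subdivision level, >= 0; default 3
#'   (642 vertices, 1280 faces).
#' @param scale_mm full extents in mm along x, y, z.
#' @return a \code{tri_mesh} centered at the origin.
#' @export
make_brain_mesh <- function(subdivisions = 3L, scale_mm = c(140, 170, 120)) {
  if (subdivisions < 0) stop("subdivisions must be >= 0")
  m <- icosphere(as.integer(subdivisions))
  v <- sweep(m$vertices, 2L, scale_mm / 2, "*")
  tri_mesh(v, m$faces)
}

# project a point radially (from the mesh centroid) onto the surface
project_radial <- function(mesh, point, ctr, far) {
  u <- point - ctr
  nu <- sqrt(sum(u * u))
  if (nu < 1e-9) stop("placement error: point at the mesh centroid")
  u <- u / nu
  hit <- intersect_ray(list(origin = ctr + u * far, direction = -u), mesh)
  if (is.null(hit)) stop("placement error: projection ray missed the mesh")
  hit
}

#' Electrode strip stepped along the mesh surface
#'
#' Emulates a subdural strip array: starting from \code{start_point}
#' projected onto the surface, contacts are stepped along the surface in the
#' tangent direction at the requested spacing. Each candidate is projected
#' back to the mesh by ray casting from outside, and the step length is
#' solved so the chord distance between consecutive contacts equals
#' \code{spacing_mm} (to 1e-3 mm on smooth surfaces).
#'
#' @param mesh a closed, star-shaped \code{tri_mesh}.
#' @param n_contacts number of contacts, >= 1.
#' @param spacing_mm inter-contact spacing in mm, > 0; default 10 (typical
#'   clinical strip pitch).
#' @param start_point approximate 3D position of the first contact (it is
#'   projected onto the surface).
#' @param direction approximate direction of travel (projected onto the
#'   local tangent plane at each step).
#' @param labels contact labels; default "1".."n".
#' @return an \code{electrode_set} with all contacts on the surface.
#' @export
make_strip <- function(mesh, n_contacts, spacing_mm = 10, start_point,
                       direction, labels = NULL) {
  if (n_contacts < 1) stop("n_contacts must be >= 1")
  if (spacing_mm <= 0) stop("spacing_mm must be > 0")
  ctr <- colMeans(mesh$vertices)
  far <- 3 * max(row_norms(sweep(mesh$vertices, 2L, ctr)))
  pts <- matrix(NA_real_, n_contacts, 3L)
  hit <- project_radial(mesh, start_point, ctr, far)
  pts[1L, ] <- hit$point
  dir <- normalize3(as.numeric(direction))
  nrm_at <- function(face) face_normals(mesh)[face, ]
  fn <- face_normals(mesh)
  cur_face <- hit$face
  for (i in seq_len(n_contacts - 1L)) {
    nrm <- fn[cur_face, ]
    tang <- dir - sum(dir * nrm) * nrm
    nt <- sqrt(sum(tang * tang))
    if (nt < 1e-9)
      stop("placement error: direction is normal to the surface")
    tang <- tang / nt
    chord_at <- function(s) {
      h <- project_radial(mesh, pts[i, ] + s * tang, ctr, far)
      sqrt(sum((h$point - pts[i, ])^2)) - spacing_mm
    }
    lo <- 0.25 * spacing_mm; hi <- 3 * spacing_mm
    flo <- chord_at(lo); fhi <- chord_at(hi)
    if (flo > 0 || fhi < 0)
      stop("placement error: cannot achieve the requested spacing ",
           "(strip may run off the surface)")
    s <- stats::uniroot(chord_at, c(lo, hi), tol = 1e-4)$root
    h <- project_radial(mesh, pts[i, ] + s * tang, ctr, far)
    pts[i + 1L, ] <- h$point
    dir <- normalize3(h$point - pts[i, ])
    cur_face <- h$face
  }
  electrode_set(pts, labels = labels)
}

#' The four-strip case-study montage
#'
#' Reproduces the shape of a clinical language-mapping implantation: four
#' 16-contact subdural strips (64 channels) on the left-lateral aspect of
#' the surface, running roughly anterior-to-posterior at descending heights
#' -- from a superior frontal-to-precentral course (channels 1-16) down to
#' an inferior frontal-to-posterior-temporal course (channels 49-64).
#' Contacts are numbered 1..64 in strip order.
#'
#' @param mesh a brain-like \code{tri_mesh}; default
#'   \code{make_brain_mesh()}.
#' @param spacing_mm contact spacing within each strip.
#' @return an \code{electrode_set} with 64 contacts.
#' @export
make_case_study_montage <- function(mesh = make_brain_mesh(),
                                    spacing_mm = 10) {
  ext <- apply(mesh$vertices, 2L, max) - apply(mesh$vertices, 2L, min)
  sc <- ext / c(140, 170, 120)
  starts <- rbind(c(-60, 58, 38), c(-62, 58, 18), c(-64, 58, -2),
                  c(-60, 62, -14))
  dirs <- rbind(c(0, -1, 0.10), c(0, -1, 0), c(0, -1, -0.10),
                c(0, -1, -0.35))
  sets <- lapply(1:4, function(s) {
    st <- starts[s, ] * sc
    make_strip(mesh, 16L, spacing_mm, start_point = st,
               direction = dirs[s, ],
               labels = as.character((s - 1L) * 16L + 1:16))
  })
  pos <- do.call(rbind, lapply(sets, electrode_positions))
  electrode_set(pos, labels = as.character(1:64))
}

# Best & Fisher (1979) rejection sampler for von Mises(0, kappa)
rvonmises <- function(n, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

# numeric quantile function of von Mises(0, kappa); wrapped-normal
# approximation for very concentrated distributions
qvonmises <- function(p, kappa) {
  if (kappa < 1e-8) return(2 * pi * p - pi)
  if (kappa > 50) {
    q <- stats::qnorm(p, sd = 1 / sqrt(kappa))
    return(pmin(pi, pmax(-pi, q)))
  }
  th <- seq(-pi, pi, length.out = 8193)
  dens <- exp(kappa * (cos(th) - 1))
  cdf <- cumsum(c(0, (dens[-1] + dens[-length(dens)]) / 2 * diff(th)))
  cdf <- cdf / cdf[length(cdf)]
  stats::approx(cdf, th, xout = p, ties = "ordered")$y
}

#' Signal pair with a known degree of phase locking
#'
#' Generates a two-channel sinusoidal recording whose instantaneous phase
#' difference is a stationary process with an exactly von Mises(0, kappa)
#' marginal, so the population phase-locking value is the Bessel ratio
#' \code{I1(kappa) / I0(kappa)}. The phase-difference process is built by
#' mapping a narrowband (low-pass) Gaussian process through the von Mises
#' quantile function: the narrow modulation bandwidth keeps the pair's
#' analytic-signal phases faithful, so the PLV estimator recovers the
#' closed-form value (a per-sample independent phase jitter would be
#' distorted by the one-sided spectral projection). kappa = 0 gives
#' uniform phase differences (PLV ~ 0); large kappa approaches PLV = 1.
#'
#' @param kappa von Mises concentration, >= 0.
#' @param fs sampling rate, Hz.
#' @param duration_s record length in seconds.
#' @param carrier_hz carrier frequency; default fs/4, keeping modulation
#'   sidebands well inside (0, fs/2).
#' @param seed RNG seed for reproducibility (NULL = use current RNG state).
#' @param copula_bw_hz bandwidth of the Gaussian copula process driving the
#'   phase difference.
#' @return a two-channel \code{recording}; the realized phase differences
#'   are stored in attribute \code{"delta_phase"}.
#' @export
make_coupled_pair <- function(kappa, fs = 250, duration_s = 400,
                              carrier_hz = fs / 4, seed = NULL,
                              copula_bw_hz = 8) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- round(fs * duration_s)
  tt <- (0:(n - 1)) / fs
  flt <- signal::butter(4, copula_bw_hz / (fs / 2), type = "low")
  g <- filtfilt_padded(flt, stats::rnorm(n + 2000), 1000)
  g <- g[1001:(n + 1000)]
  g <- (g - mean(g)) / stats::sd(g)
  if (kappa > 1e6) {
    d <- numeric(n)
  } else {
    d <- qvonmises(stats::pnorm(g), kappa)
  }
  ph1 <- 2 * pi * carrier_hz * tt
  rec <- recording(rbind(cos(ph1), cos(ph1 + d)), fs)
  attr(rec, "delta_phase") <- d
  rec
}

#' ERP-structured multichannel recording
#'
#' Emulates a stimulus-response recording: every channel carries a known
#' template waveform (a damped 8 Hz oscillation starting 200 ms after each
#' stimulus onset, scaled by a per-channel gain) plus white noise at the
#' requested SNR. Events are placed with jittered inter-trial intervals
#' long enough that every epoch window (-800 to +3500 ms) fits inside the
#' recording without overlap. Optionally, groups of channels share
#' narrowband oscillatory sources, creating phase-locked clusters for
#' connectivity analysis, and a few trials can carry large-amplitude
#' artifacts to exercise epoch rejection.
#'
#' @param n_trials number of stimulus events, >= 1.
#' @param n_channels channel count.
#' @param fs sampling rate, Hz (default 600, supporting analysis up to
#'   250 Hz with margin).
#' @param snr template RMS over noise SD on the active window;
#'   \code{Inf} = noiseless.
#' @param seed RNG seed (NULL = current RNG state).
#' @param coupled_groups list of channel-index vectors; channels within a
#'   group share band-limited sources (default NULL = none).
#' @param coupling_bands list of c(lo, hi) bands for the shared sources.
#' @param coupling_strength amplitude of shared sources relative to the
#'   noise SD.
#' @param artifact_trials how many trials receive an injected artifact.
#' @param artifact_scale artifact amplitude in noise-SD units.
#' @return a \code{recording} with events; attributes \code{"template"}
#'   (the epoch-aligned noiseless template, channels x epoch samples for
#'   the -800..+3500 ms window), \code{"gains"} and
#'   \code{"artifact_trials"}.
#' @export
make_erp_dataset <- function(n_trials = 40, n_channels = 64, fs = 600,
                             snr = 1, seed = NULL, coupled_groups = NULL,
                             coupling_bands = list(c(4, 8), c(30, 80)),
                             coupling_strength = 0.8,
                             artifact_trials = 0, artifact_scale = 25) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  pre_s <- 0.8; post_s <- 3.5
  tpl_t <- (0:(round(post_s * fs) - 1)) / fs
  template1 <- ifelse(tpl_t >= 0.2,
                      exp(-(tpl_t - 0.2) / 0.6) *
                        sin(2 * pi * 8 * (tpl_t - 0.2)),
                      0)
  gains <- stats::runif(n_channels, 0.5, 1.5)
  iti <- post_s + pre_s + 0.2 + stats::runif(n_trials, 0, 0.5)
  onsets <- round((pre_s + 0.2 + cumsum(c(0, iti[-n_trials]))) * fs) + 1L
  nsamp <- onsets[n_trials] + round((post_s + 0.3) * fs)
  tpl_rms <- sqrt(mean(template1[tpl_t >= 0.2]^2))
  noise_sd <- if (is.infinite(snr)) 0 else mean(gains) * tpl_rms / snr
  data <- if (noise_sd > 0)
    matrix(stats::rnorm(n_channels * nsamp, sd = noise_sd), n_channels)
  else matrix(0, n_channels, nsamp)
  if (!is.null(coupled_groups) && noise_sd > 0) {
    for (grp in coupled_groups) {
      for (band in coupling_bands) {
        flt <- signal::butter(4, band / (fs / 2), type = "pass")
        src <- filtfilt_padded(flt, stats::rnorm(nsamp + 2000), 1000)
        src <- src[1001:(nsamp + 1000)]
        src <- src / stats::sd(src)
        wts <- seq(1, 0.4, length.out = length(grp))
        data[grp, ] <- data[grp, ] +
          coupling_strength * noise_sd * outer(wts, src)
      }
    }
  }
  for (tr in seq_len(n_trials)) {
    idx <- onsets[tr] + seq_along(template1) - 1L
    data[, idx] <- data[, idx] + outer(gains, template1)
  }
  art <- integer(0)
  if (artifact_trials > 0 && noise_sd > 0) {
    art <- sort(sample(n_trials, min(artifact_trials, n_trials)))
    blip_t <- (0:(round(0.5 * fs) - 1)) / fs
    blip <- artifact_scale * noise_sd * sin(pi * blip_t / 0.5)
    for (tr in art) {
      idx <- onsets[tr] + round(fs) + seq_along(blip) - 1L
      data[, idx] <- data[, idx] + rep(blip, each = n_channels)
    }
  }
  rec <- recording(data, fs, events = onsets)
  npre <- round(pre_s * fs)
  attr(rec, "template") <- cbind(matrix(0, n_channels, npre),
                                 outer(gains, template1))
  attr(rec, "gains") <- gains
  attr(rec, "artifact_trials") <- art
  rec
}
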