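# Seeded synthetic-data generators with ground truth.
#
# The PSM generator builds peptidoform groups over the in silico Arg-C
# digest of the histone H3 N-terminal tail (residues 1-43, propionylated
# scheme), places true identifications' retention times in blocks obeying
# the modification elution order, and turns a configurable fraction of
# members into violators whose RT block sits on the wrong side of the
# chain. Violator PEPs stochastically dominate true PEPs (disjoint
# ranges: 0.2-0.4 vs 0.0001-0.002), so the greedy filter always sees true
# forms first and most violator q-values sit above a stringent FDR gate.

H3_TAIL <- "ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRYRP"

# chain of lysine states used for group construction, with RT block
# offsets (minutes) honouring ub < me2 <= me3 < ac < prop < me
SYN_CHAIN <- data.frame(
  state = c("ub", "me2", "me3", "ac", "none", "me"),
  offset = c(0, 4, 6, 10, 14, 18),
  stringsAsFactors = FALSE
)

# deterministic substream seed for generator k
substream <- function(seed, k) {
  as.integer((as.numeric(seed) * 97 + k) %% 2147483647)
}

#' Default synthetic peptide universe
#'
#' Arg-C digest of the H3 tail (residues 1-43) restricted to search-length
#' peptides containing at least one lysine.
#'
#' @return Data frame with `peptide` (unmodified sequence), `start`, `end`,
#'   and `ksite` (position of the first lysine within the peptide).
#' @export
syn_peptide_universe <- function() {
  d <- digest(H3_TAIL, "ArgC", 0)
  d <- d[nchar(d$peptide) >= 6 & nchar(d$peptide) <= 25, , drop = FALSE]
  d$ksite <- vapply(d$peptide, function(s) {
    as.integer(regexpr("K", s))
  }, 0L, USE.NAMES = FALSE)
  d <- d[d$ksite > 0, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Generate a synthetic PSM dataset with ground truth
#'
#' Each group (one unmodified sequence from [syn_peptide_universe()])
#' carries one member per chain state at the first lysine. True members'
#' RTs sit at ordered block offsets plus Gaussian jitter; violators
#' (a `violator_fraction` subset per group) take an RT outside their valid
#' interval (late for early-chain states, early for late-chain states),
#' which is inconsistent at any tolerance below the block gap. PEP ranges
#' for violators (0.2-0.4) dominate those of true members (0.0001-0.002);
#' q-values are derived from the PEP ranking.
#'
#' @param seed Integer seed.
#' @param n_groups Number of peptide groups (capped by the universe size).
#' @param violator_fraction Fraction of each group's members made violators
#'   (in `[0, 0.5]`; above 0.5 the wrong-side construction can lose its
#'   strict anchor).
#' @param jitter_sd RT jitter SD in minutes, applied per scan.
#' @param scans_per_peptide MS/MS scans per peptidoform.
#' @return List with `psms` (a `psm_table`-shaped data frame) and `truth`
#'   (columns `peptide`, `sequence`, `state`, `is_violator`, `base_rt`).
#' @export
gen_psm_dataset <- function(seed = 1L, n_groups = 4L,
                            violator_fraction = 0, jitter_sd = 0,
                            scans_per_peptide = 2L) {
  if (violator_fraction < 0 || violator_fraction > 1) {
    stop("violator_fraction must lie in [0, 1]")
  }
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  set.seed(substream(seed, 1L))
  uni <- syn_peptide_universe()
  uni <- uni[seq_len(min(n_groups, nrow(uni))), , drop = FALSE]
  chain <- SYN_CHAIN
  nst <- nrow(chain)
  psms <- list(); truth <- list()
  psm_i <- 0L
  for (g in seq_len(nrow(uni))) {
    seqs <- uni$peptide[g]
    ksite <- uni$ksite[g]
    base_rt <- 20 + 25 * (g - 1)
    nviol <- round(violator_fraction * nst)
    viol_idx <- if (nviol > 0) sample(nst, nviol) else integer()
    for (j in seq_len(nst)) {
      st <- chain$state[j]
      mods <- if (st == "none") character() else
        stats::setNames(st, as.character(ksite))
      pstr <- format_peptide(modified_peptide(seqs, mods))
      is_viol <- j %in% viol_idx
      rt0 <- if (!is_viol) {
        base_rt + chain$offset[j]
      } else if (j <= nst / 2) {
        base_rt + max(chain$offset) + 4   # too late for an early state
      } else {
        base_rt - 4                       # too early for a late state
      }
      pep <- if (is_viol) stats::runif(1, 0.2, 0.4) else
        stats::runif(1, 0.0001, 0.002)
      for (s in seq_len(scans_per_peptide)) {
        psm_i <- psm_i + 1L
        rt <- rt0 + if (jitter_sd > 0) stats::rnorm(1, 0, jitter_sd) else 0
        psms[[psm_i]] <- data.frame(
          psm_id = sprintf("psm%05d", psm_i),
          spectrum_id = sprintf("scan%05d", psm_i),
          rt = max(rt, 0), charge = 2L, peptide = pstr,
          xcorr = round(4 - 2 * pep, 4), rank = 1L,
          pep = pep, q_value = NA_real_, sample = "HeDNA",
          stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1]] <- data.frame(
        peptide = pstr, sequence = seqs, state = st,
        is_violator = is_viol, base_rt = rt0, pep = pep,
        stringsAsFactors = FALSE)
    }
  }
  psms <- do.call(rbind, psms)
  # q-values from the PEP ranking: q(i) = min over j >= i of mean PEP of
  # the j best PSMs
  ord <- order(psms$pep)
  cm <- cumsum(psms$pep[ord]) / seq_along(ord)
  q <- rev(cummin(rev(cm)))
  psms$q_value[ord] <- q
  attr(psms, "scheme") <- "propionylated"
  class(psms) <- c("psm_table", "data.frame")
  list(psms = psms, truth = do.call(rbind, truth))
}

#' Generate synthetic Gaussian XIC traces with known areas
#'
#' @param seed Integer seed (reserved; traces are noiseless by default).
#' @param peaks Data frame with columns `peptide`, `charge`, `sample`,
#'   `center` (min), `sigma` (min, > 0), `amplitude`.
#' @param step Sampling step, minutes.
#' @param halfwidth Window half-width in sigmas around each center.
#' @param noise_sd Additive Gaussian intensity noise SD (truncated at 0).
#' @return List with `xics` (long data frame: `peptide`, `charge`,
#'   `sample`, `time_min`, `intensity`) and `truth` (the peaks plus
#'   `true_area = amplitude * sigma * sqrt(2*pi)`).
#' @export
gen_xic <- function(seed = 1L, peaks, step = 0.005, halfwidth = 6,
                    noise_sd = 0) {
  if (any(peaks$sigma <= 0)) stop("sigma must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(substream(seed, 2L))
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    p <- peaks[i, ]
    tt <- seq(p$center - halfwidth * p$sigma,
              p$center + halfwidth * p$sigma, by = step)
    y <- p$amplitude * exp(-(tt - p$center)^2 / (2 * p$sigma^2))
    if (noise_sd > 0) y <- pmax(y + stats::rnorm(length(y), 0, noise_sd), 0)
    data.frame(peptide = p$peptide, charge = p$charge, sample = p$sample,
               time_min = tt, intensity = y, stringsAsFactors = FALSE)
  })
  truth <- peaks
  truth$true_area <- peaks$amplitude * peaks$sigma * sqrt(2 * pi)
  list(xics = do.call(rbind, rows), truth = truth)
}

#' Generate a synthetic one-site FP titration
#'
#' A 12-point semi-log concentration grid spanning `span` times Kd on each
#' side, anisotropy from the one-site hyperbola plus Gaussian noise given
#' in mP (divided by 1000 on the anisotropy scale).
#'
#' @param seed Integer seed.
#' @param kd True dissociation constant, molar (> 0).
#' @param a_free,a_bound Anisotropy endpoints (defaults 0.07/0.20, typical
#'   of a 10 nM FAM tracer experiment).
#' @param n Number of points (>= 4).
#' @param noise_mp Gaussian noise SD in milli-polarization units
#'   (default 2).
#' @param span Concentration range: `kd/span[1]` ... `kd*span[2]` with
#'   `span = c(100, 100)` meaning 0.01x-100x Kd.
#' @return List with `titration` (data frame `conc_M`, `anisotropy`) and
#'   `truth` (`kd`, `a_free`, `a_bound`).
#' @export
gen_fp_titration <- function(seed = 1L, kd = 1e-6, a_free = 0.07,
                             a_bound = 0.20, n = 12L, noise_mp = 2,
                             span = c(100, 100)) {
  if (kd <= 0) stop("kd must be > 0")
  if (n < 4) stop("need at least 4 points")
  set.seed(substream(seed, 3L))
  conc <- 10^seq(log10(kd / span[1]), log10(kd * span[2]), length.out = n)
  a <- one_site_curve(conc, kd, a_free, a_bound)
  if (noise_mp > 0) a <- a + stats::rnorm(n, 0, noise_mp / 1000)
  list(titration = data.frame(conc_M = conc, anisotropy = a),
       truth = list(kd = kd, a_free = a_free, a_bound = a_bound))
}

#' Generate a linear time course
#'
#' @param seed Integer seed.
#' @param slope,intercept Line parameters (units/min, units).
#' @param times Sampling times, minutes.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @return List with `timecourse` (data frame `t_min`, `intensity`) and
#'   `truth` (`slope`, `intercept`).
#' @export
gen_timecourse <- function(seed = 1L, slope = 10, intercept = 0,
                           times = seq(0, 20, by = 2), noise_sd = 0) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(substream(seed, 4L))
  y <- intercept + slope * times
  if (noise_sd > 0) y <- y + stats::rnorm(length(times), 0, noise_sd)
  list(timecourse = data.frame(t_min = times, intensity = y),
       truth = list(slope = slope, intercept = intercept))
}

#' Generate a two-channel image with a closed-form 5mC score
#'
#' Builds an `nrow x ncol` image in which `m` pixels are nuclear
#' (`b = b0 > t`), of which `k` carry 5mC signal `r0 > t`; everything else
#' is zero. The analytic score is `k * (r0 - t) / m`.
#'
#' @param seed Integer seed.
#' @param nrow,ncol Image dimensions.
#' @param m Number of nuclear pixels (`b > t`).
#' @param k Number of signal pixels among the nuclear ones (`k <= m`).
#' @param r0 Signal intensity (> t).
#' @param b0 Nuclear intensity (> t).
#' @param t Background threshold.
#' @return List with `image` (a [two_channel_image()]) and `truth`
#'   (`score = k * (r0 - t) / m`).
#' @export
gen_images <- function(seed = 1L, nrow = 64L, ncol = 64L, m = 400L,
                       k = 120L, r0 = 50, b0 = 80, t = 10) {
  stopifnot(k <= m, m <= nrow * ncol, r0 > t, b0 > t)
  set.seed(substream(seed, 5L))
  npix <- nrow * ncol
  nuclear <- sample(npix, m)
  signal <- sample(nuclear, k)
  b <- matrix(0, nrow, ncol); b[nuclear] <- b0
  r <- matrix(0, nrow, ncol); r[signal] <- r0
  list(image = two_channel_image(r, b, t),
       truth = list(score = k * (r0 - t) / m, k = k, m = m))
}

#' Generate Gaussian-distributed AFM particle volumes
#'
#' @param seed Integer seed.
#' @param n Number of particles.
#' @param mean,sd Volume distribution parameters (nm^3).
#' @return List with `volumes` (numeric vector) and `truth` (`mean`, `sd`).
#' @export
gen_afm_volumes <- function(seed = 1L, n = 5000L, mean = 100, sd = 15) {
  if (sd < 0) stop("sd must be >= 0")
  set.seed(substream(seed, 6L))
  list(volumes = stats::rnorm(n, mean, sd),
       truth = list(mean = mean, sd = sd))
}
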