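#' Event-type probabilities for energy deposited in the target volume
#'
#' Each damage-capable event in the 5 x 5 nm target is assigned one of four
#' outcomes: `p_a`, direct ionization of a sugar-phosphate moiety producing a
#' single-strand break (SSB); `p_b`, ionization of water producing an OH
#' radical; `p_c`, direct ionization of a DNA base producing base damage (BD);
#' `p_d`, energy imparted to histones or other molecules, producing no lesion.
#' The defaults reflect the approximate mass fractions of the components of a
#' nucleosome-scale volume.
#'
#' @param p_a,p_b,p_c,p_d Probabilities in `[0, 1]` summing to 1.
#' @return An object of class `event_probabilities` (a named list).
#' @examples
#' event_probabilities()
#' event_probabilities(0.25, 0.25, 0.2, 0.3)
#' @export
event_probabilities <- function(p_a = 0.2, p_b = 0.2, p_c = 0.2, p_d = 0.4) {
  p <- c(p_a = p_a, p_b = p_b, p_c = p_c, p_d = p_d)
  if (!is.numeric(p) || length(p) != 4L || anyNA(p)) {
    stop("event probabilities must be four non-missing numbers", call. = FALSE)
  }
  if (any(p < 0 | p > 1)) {
    stop("event probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-12) {
    stop("event probabilities must sum to 1 (within 1e-12), got ",
         format(sum(p), digits = 15), call. = FALSE)
  }
  structure(as.list(p), class = "event_probabilities")
}

#' @export
print.event_probabilities <- function(x, ...) {
  cat("<event_probabilities>  p_A =", x$p_a, " p_B =", x$p_b,
      " p_C =", x$p_c, " p_D =", x$p_d, "\n")
  invisible(x)
}

#' OH-radical fate probabilities
#'
#' An OH radical produced by a type-B event converts to a strand break with
#' probability `r1`, to a base damage with probability `r2`, or produces no
#' lesion (`r3 = 1 - r1 - r2`). Defaults are the standard estimates
#' `r1 = 0.13`, `r2 = 0.52`.
#'
#' @param r1 Probability of conversion to an SSB.
#' @param r2 Probability of conversion to a BD.
#' @param r3 Probability of no lesion; defaults to `1 - r1 - r2`.
#' @return An object of class `radical_fates`.
#' @seealso [radical_fates_from_attack()] for the derivation of the defaults.
#' @export
radical_fates <- function(r1 = 0.13, r2 = 0.52, r3 = 1 - r1 - r2) {
  r <- c(r1 = r1, r2 = r2, r3 = r3)
  if (!is.numeric(r) || length(r) != 3L || anyNA(r)) {
    stop("radical fates must be three non-missing numbers", call. = FALSE)
  }
  if (any(r < -1e-12 | r > 1 + 1e-12)) {
    stop("radical fate probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(r) - 1) > 1e-12) {
    stop("radical fate probabilities must sum to 1 (within 1e-12)", call. = FALSE)
  }
  structure(as.list(pmin(pmax(r, 0), 1)), class = "radical_fates")
}

#' Derive radical fates from attack-site fractions
#'
#' OH radicals attack sugar-phosphate moieties or bases in proportion to
#' `sugar_fraction` and `base_fraction`; an attack converts to an actual
#' lesion (SSB or BD respectively) with probability `conversion`. With the
#' default 20%/80% split and 65% conversion this gives `r1 = 0.13` and
#' `r2 = 0.52`.
#'
#' @param sugar_fraction Fraction of OH attacks on sugar-phosphate moieties.
#' @param base_fraction Fraction of OH attacks on bases.
#' @param conversion Probability that an attack yields a lesion.
#' @return A [radical_fates()] object.
#' @export
radical_fates_from_attack <- function(sugar_fraction = 0.2,
                                      base_fraction = 0.8,
                                      conversion = 0.65) {
  if (abs(sugar_fraction + base_fraction - 1) > 1e-12) {
    stop("attack-site fractions must sum to 1", call. = FALSE)
  }
  if (conversion < 0 || conversion > 1) {
    stop("`conversion` must lie in [0, 1]", call. = FALSE)
  }
  radical_fates(r1 = sugar_fraction * conversion,
                r2 = base_fraction * conversion)
}

#' @export
print.radical_fates <- function(x, ...) {
  cat("<radical_fates>  r1 =", x$r1, " r2 =", x$r2, " r3 =", x$r3, "\n")
  invisible(x)
}

#' Smeared energy threshold per damage-capable event
#'
#' The energy imparted needed per elemental damage event is modelled as a
#' normal distribution (mean 17.5 eV, sd 5 eV) truncated below at
#' `lower_cut_ev`, realized as a fixed quadrature of `n_nodes` nodes
#' (see [threshold_nodes()]). `sd_ev = 0` degenerates to a point threshold.
#'
#' @param mean_ev Mean threshold energy in eV (> 0).
#' @param sd_ev Standard deviation in eV (>= 0).
#' @param lower_cut_ev Lower truncation in eV (> 0); thresholds below this are
#'   unphysical (OH production itself needs ~13 eV).
#' @param n_nodes Number of quadrature nodes (>= 1).
#' @return An object of class `threshold_distribution`.
#' @export
threshold_distribution <- function(mean_ev = 17.5, sd_ev = 5,
                                   lower_cut_ev = 7.5, n_nodes = 9L) {
  if (!is.numeric(mean_ev) || length(mean_ev) != 1L || mean_ev <= 0) {
    stop("`mean_ev` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(sd_ev) || length(sd_ev) != 1L || sd_ev < 0) {
    stop("`sd_ev` must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(lower_cut_ev) || length(lower_cut_ev) != 1L || lower_cut_ev <= 0) {
    stop("`lower_cut_ev` must be a single positive number", call. = FALSE)
  }
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 1L) {
    stop("`n_nodes` must be an integer >= 1", call. = FALSE)
  }
  structure(list(mean_ev = mean_ev, sd_ev = sd_ev,
                 lower_cut_ev = lower_cut_ev, n_nodes = n_nodes),
            class = "threshold_distribution")
}

#' @export
print.threshold_distribution <- function(x, ...) {
  cat("<threshold_distribution>  mean =", x$mean_ev, "eV  sd =", x$sd_ev,
      "eV  cut =", x$lower_cut_ev, "eV  nodes =", x$n_nodes, "\n")
  invisible(x)
}

#' Default base-pair clustering ladder q0(J)
#'
#' Monte-Carlo estimates (73 bp segment, 10 bp window) of the probability that
#' the J-th strand break does not join an existing cluster, for J = 2..7.
#' These printed values are the normative default; see [estimate_q0()] for
#' re-estimating them under explicit placement conventions.
#'
#' @return Named numeric vector, names "2".."7".
#' @export
q0_ladder_default <- function() {
  c(`2` = 0.87, `3` = 0.74, `4` = 0.60, `5` = 0.475, `6` = 0.35, `7` = 0.12)
}

#' Segment geometry and clustering probabilities
#'
#' Describes the DNA segment (length `n_bp`, clustering window `window_bp`)
#' and the ladder of no-cluster probabilities `q0(J)` used when the J-th
#' strand break is added. Within the window, attachment on the same or the
#' opposite strand is equally probable, so each attachment branch carries
#' weight `q1(J) = (1 - q0(J)) / 2` and `q0 + 2 q1 = 1` holds exactly.
#'
#' Values of `q0(J)` outside the supplied ladder follow: `q0(1) = 1` (a first
#' break cannot cluster) and, for J beyond the ladder, linear extrapolation of
#' its last two entries clipped at 0 (with the default ladder, `q0 = 0` from
#' J = 8 on: large clusters capture every further break).
#'
#' @param n_bp Segment length in base pairs.
#' @param window_bp Clustering window in base pairs (breaks within this
#'   distance form one lesion).
#' @param q0 Named numeric vector `q0(J)` for consecutive J starting at 2,
#'   non-increasing, each in `[0, 1]`.
#' @param q0_constant Optional single probability; when set, `q0` is held at
#'   this constant for every step. This symbolic mode reproduces the
#'   closed-form operator expansions and is used for coefficient checks.
#' @return An object of class `cluster_geometry`.
#' @examples
#' geom <- cluster_geometry()
#' q0_of(geom, 1:9)
#' @export
cluster_geometry <- function(n_bp = 73L, window_bp = 10L,
                             q0 = q0_ladder_default(),
                             q0_constant = NULL) {
  n_bp <- as.integer(n_bp)
  if (is.na(n_bp) || n_bp < 1L) stop("`n_bp` must be a positive integer", call. = FALSE)
  if (!is.numeric(window_bp) || length(window_bp) != 1L || window_bp < 0) {
    stop("`window_bp` must be a single non-negative number", call. = FALSE)
  }
  if (!is.null(q0_constant)) {
    if (!is.numeric(q0_constant) || length(q0_constant) != 1L ||
        q0_constant < 0 || q0_constant > 1) {
      stop("`q0_constant` must be a single probability", call. = FALSE)
    }
  }
  if (!is.numeric(q0) || length(q0) < 1L || anyNA(q0)) {
    stop("`q0` must be a non-missing numeric vector", call. = FALSE)
  }
  if (any(q0 < 0 | q0 > 1)) stop("q0 values must lie in [0, 1]", call. = FALSE)
  if (is.unsorted(rev(q0), strictly = FALSE)) {
    stop("q0 must be non-increasing in J", call. = FALSE)
  }
  if (is.null(names(q0))) names(q0) <- seq.int(2L, length.out = length(q0))
  j <- as.integer(names(q0))
  if (anyNA(j) || j[1] != 2L || (length(j) > 1 && any(diff(j) != 1L))) {
    stop("`q0` must be named by consecutive integers starting at 2", call. = FALSE)
  }
  # precompute the extended ladder up to a generous J, extrapolating linearly
  j_hi <- 64L
  ext <- numeric(j_hi)
  ext[1] <- 1
  ext[j] <- q0
  if (max(j) < j_hi) {
    if (length(q0) >= 2) {
      slope <- q0[length(q0)] - q0[length(q0) - 1L]
    } else {
      slope <- 0
    }
    jj <- (max(j) + 1L):j_hi
    ext[jj] <- pmax(0, q0[length(q0)] + slope * (jj - max(j)))
  }
  structure(list(n_bp = n_bp, window_bp = window_bp, q0_table = q0,
                 q0_constant = q0_constant, q0_extended = ext),
            class = "cluster_geometry")
}

#' No-cluster probability for the k-th strand break
#'
#' @param geom A [cluster_geometry()].
#' @param k Integer vector: index of the break being added (the k-th SSB).
#' @return Numeric vector of `q0(k)` values.
#' @export
q0_of <- function(geom, k) {
  stopifnot(inherits(geom, "cluster_geometry"))
  k <- as.integer(k)
  if (anyNA(k) || any(k < 1L)) stop("`k` must be integers >= 1", call. = FALSE)
  if (!is.null(geom$q0_constant)) {
    return(rep(geom$q0_constant, length(k)))
  }
  geom$q0_extended[pmin(k, length(geom$q0_extended))]
}

#' Per-strand attachment probability for the k-th strand break
#'
#' @inheritParams q0_of
#' @return `q1(k) = (1 - q0(k)) / 2`.
#' @export
q1_of <- function(geom, k) (1 - q0_of(geom, k)) / 2

#' @export
print.cluster_geometry <- function(x, ...) {
  cat("<cluster_geometry> ", x$n_bp, "bp segment, window", x$window_bp, "bp\n")
  if (!is.null(x$q0_constant)) {
    cat("  q0 held constant at", x$q0_constant, "(symbolic mode)\n")
  } else {
    cat("  q0(J):", paste0(names(x$q0_table), "=", x$q0_table, collapse = "  "), "\n")
  }
  invisible(x)
}

#' Full clustered-damage model parameter set
#'
#' Bundles the event-type probabilities, radical fates, segment geometry,
#' threshold distribution, propagation mode and the event-number cap into one
#' object consumed by [damage_probabilities()], [yield_per_gy()] and friends.
#'
#' @param events An [event_probabilities()] object.
#' @param fates A [radical_fates()] object.
#' @param geometry A [cluster_geometry()] object.
#' @param thresholds A [threshold_distribution()] object.
#' @param mode `"exact"` (full weighted-state propagation, the default) or
#'   `"paper_approx"` (closed-form high-order truncations: OH-radical break
#'   terms kept to second order, attachment tiers beyond the third power of q1
#'   tallied into the complex-DSB route).
#' @param j_cap Maximum number of events considered; energies implying more
#'   events are clamped to this order.
#' @return An object of class `damage_model`.
#' @examples
#' model <- damage_model()
#' damage_probabilities(model, j_tot = 2)
#' @export
damage_model <- function(events = event_probabilities(),
                         fates = radical_fates(),
                         geometry = cluster_geometry(),
                         thresholds = threshold_distribution(),
                         mode = c("exact", "paper_approx"),
                         j_cap = 30L) {
  stopifnot(inherits(events, "event_probabilities"),
            inherits(fates, "radical_fates"),
            inherits(geometry, "cluster_geometry"),
            inherits(thresholds, "threshold_distribution"))
  mode <- match.arg(mode)
  j_cap <- as.integer(j_cap)
  if (is.na(j_cap) || j_cap < 0L) stop("`j_cap` must be a non-negative integer", call. = FALSE)
  structure(list(events = events, fates = fates, geometry = geometry,
                 thresholds = thresholds, mode = mode, j_cap = j_cap),
            class = "damage_model")
}

#' @export
print.damage_model <- function(x, ...) {
  cat("<damage_model>  mode =", x$mode, "  j_cap =", x$j_cap, "\n")
  print(x$events); print(x$fates); print(x$geometry); print(x$thresholds)
  invisible(x)
}
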