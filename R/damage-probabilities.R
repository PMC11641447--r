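# Marginal summaries over event compositions.
#
# Key factorization: conditional on the number s of B events whose radical
# converts to a strand break, the lesion configuration is the pure
# break-addition chain of length j_a + s (break additions from A events and
# from converted radicals are identical operations), and the base-damage
# count from the remaining B events is an independent binomial. The per-J
# table therefore needs only the j_max + 1 pure-break spectra plus cheap
# binomial mixtures, instead of propagating a joint (lesions x bd) state.
# resolve_composition() keeps the direct step-wise propagation, which tests
# compare against this factorized path.

.core_stat_names <- c("p_ssb_s", "p_ssb_s2", "p_ssb_plus", "p_ssb_pp",
                      "p_dsb_s", "p_dsb_plus", "p_dsb_pp", "p_dsb_any",
                      "e_ssb_s", "e_ssb_breaks", "e_ssb_lesions",
                      "e_dsb_s", "e_dsb_plus", "e_dsb_pp", "e_dsb_lesions")

lspec_stats_base <- function(sp) {
  M <- sp$counts
  p <- sp$prob
  iso <- M[, "ssb_s"]; splus <- M[, "ssb_plus"]
  spp <- M[, "ssb_pp"]; sppp <- M[, "ssb_ppp"]
  ds <- M[, "dsb_s"]; dpl <- M[, "dsb_plus"]; dpp <- M[, "dsb_pp"]
  bd0 <- M[, "bd"]
  dsb_n <- ds + dpl + dpp
  max_bd <- if (length(bd0)) max(bd0) else 0
  bd_dist <- vapply(0:max_bd, function(v) sum(p[bd0 == v]), numeric(1))
  list(
    core = c(
      p_ssb_s = sum(p[iso == 1]),
      p_ssb_s2 = sum(p[iso >= 2]),
      p_ssb_plus = sum(p[splus >= 1]),
      p_ssb_pp = sum(p[(spp + sppp) >= 1]),
      p_dsb_s = sum(p[ds >= 1]),
      p_dsb_plus = sum(p[dpl >= 1]),
      p_dsb_pp = sum(p[dpp >= 1]),
      p_dsb_any = sum(p[dsb_n >= 1]),
      e_ssb_s = sum(p * iso),
      e_ssb_breaks = sum(p * (iso + 2 * splus + 3 * spp + 4 * sppp)),
      e_ssb_lesions = sum(p * (iso + splus + spp + sppp)),
      e_dsb_s = sum(p * ds),
      e_dsb_plus = sum(p * dpl),
      e_dsb_pp = sum(p * dpp),
      e_dsb_lesions = sum(p * dsb_n)
    ),
    bd_dist = bd_dist,
    p_dsb_bd0 = sum(p[dsb_n >= 1 & bd0 == 0]),
    p_dsb_s_bd0 = sum(p[ds >= 1 & bd0 == 0]),
    p_dsb_plus_bd0 = sum(p[dpl >= 1 & bd0 == 0]),
    p_dsb_pp_bd0 = sum(p[dpp >= 1 & bd0 == 0]),
    e_bd0 = sum(p * bd0)
  )
}

# core lesion statistics of the pure break chain, rows n = 0..n_max breaks
break_chain_core <- function(model, n_max) {
  sp <- lspec_empty()
  core <- matrix(0, nrow = n_max + 1L, ncol = length(.core_stat_names),
                 dimnames = list(NULL, .core_stat_names))
  core[1L, ] <- lspec_stats_base(sp)$core
  for (n in seq_len(n_max)) {
    sp <- lspec_add_break(sp, model$geometry, mode = model$mode)
    core[n + 1L, ] <- lspec_stats_base(sp)$core
  }
  core
}

convolve_probs <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# marginal statistics of composition (j_a, j_b, j_c), using the chain.
# Components are triples (weight, breaks from B, bd distribution), one per
# number of radical conversions s. In exact mode s ~ Binomial(j_b, r1) and
# the non-converting factors give bd ~ Binomial(j_b - s, r2 / (1 - r1)). In
# paper_approx mode terms beyond order r1^2 are rerouted: paths reaching a
# second conversion at factor t keep it and branch only bd-vs-nothing (at
# rate r2) afterwards.
compose_stats <- function(chain, fates, mode, j_a, j_b, j_c) {
  r1 <- fates$r1; r2 <- fates$r2
  rho <- if (r1 < 1) r2 / (1 - r1) else 0
  approx <- mode == "paper_approx" && j_b > 2L
  if (approx) {
    s <- c(0L, 1L, rep(2L, max(j_b - 1L, 0L)))
    t2 <- 2:j_b
    ws <- c(stats::dbinom(0L, j_b, r1), stats::dbinom(1L, j_b, r1),
            (t2 - 1) * r1^2 * (1 - r1)^(t2 - 2))
    n_rho <- c(j_b, j_b - 1L, t2 - 2L)
    n_r2 <- c(0L, 0L, j_b - t2)
  } else {
    s <- 0:j_b
    ws <- stats::dbinom(s, j_b, r1)
    n_rho <- j_b - s
    n_r2 <- rep(0L, length(s))
  }
  core <- colSums(ws * chain[j_a + s + 1L, , drop = FALSE])
  max_bd <- j_b
  bd_dist <- numeric(max_bd + 1L)
  p0_by_s <- numeric(length(s))
  for (i in seq_along(s)) {
    d <- stats::dbinom(0:n_rho[i], n_rho[i], rho)
    if (n_r2[i] > 0L) {
      d <- convolve_probs(d, stats::dbinom(0:n_r2[i], n_r2[i], r2))
    }
    p0_by_s[i] <- d[1L]
    bd_dist[seq_along(d)] <- bd_dist[seq_along(d)] + ws[i] * d
  }
  bd_vals <- 0:max_bd
  bd_at <- function(k) {
    v <- k - j_c
    if (v < 0 || v > max_bd) 0 else bd_dist[v + 1L]
  }
  # joint with zero base damage: the bd-free factor is independent of the
  # lesion configuration given s
  nb <- function(col) {
    if (j_c == 0L) sum(ws * chain[j_a + s + 1L, col] * p0_by_s) else 0
  }
  c(core,
    p_dsb_no_bd = nb("p_dsb_any"),
    p_dsb_s_no_bd = nb("p_dsb_s"),
    p_dsb_plus_no_bd = nb("p_dsb_plus"),
    p_dsb_pp_no_bd = nb("p_dsb_pp"),
    p_bd_1 = bd_at(1), p_bd_2 = bd_at(2), p_bd_3 = bd_at(3),
    p_bd_gt3 = sum(bd_dist[bd_vals + j_c > 3]),
    e_bd = sum(bd_vals * bd_dist) + j_c)
}

#' Damage-probability table over total event numbers
#'
#' For each requested `j_tot`, sums the lesion-spectrum marginals of every
#' event composition weighted by its multinomial probability, giving the
#' probabilities and expected numbers of each lesion class as a function of
#' the number of damage-capable events.
#'
#' @param model A [damage_model()].
#' @param j_tot Integer vector of total event numbers (>= 0).
#' @return A tibble with one row per `j_tot` and columns
#' \describe{
#'   \item{p_ssb_s, p_ssb_s2}{probability of exactly one / of two or more
#'     isolated SSBs}
#'   \item{p_ssb_plus, p_ssb_pp}{probability of at least one SSB+ / at least
#'     one SSB++ (>= 3 breaks, same strand; the >= 4-break class is folded in)}
#'   \item{p_dsb_s, p_dsb_plus, p_dsb_pp}{probability of at least one simple /
#'     3-break / >= 4-break DSB}
#'   \item{p_dsb_any}{probability of at least one DSB of any complexity}
#'   \item{p_dsb_no_bd}{probability of at least one DSB with no base damage in
#'     the segment}
#'   \item{p_bd_1, p_bd_2, p_bd_3, p_bd_gt3}{base-damage multiplicity
#'     probabilities}
#'   \item{e_*}{expected counts: isolated SSBs, SSB-class breaks (weighted by
#'     breaks per lesion), SSB-class lesions, DSB subclasses, DSB lesions,
#'     base damages}
#'   \item{frac_complex_ssb, frac_complex_dsb}{expected fraction of SSB-class
#'     lesions that are complex, and of DSB lesions that are DSB+/DSB++}
#'   \item{dsb_to_ssb, bd_to_ssb}{ratios of expected DSB lesions and expected
#'     base damages to expected SSB-class lesions}
#' }
#' @examples
#' damage_probability_table(damage_model(), j_tot = 0:6)
#' @export
damage_probability_table <- function(model, j_tot = 0:10) {
  stopifnot(inherits(model, "damage_model"))
  js <- sort(unique(as.integer(j_tot)))
  if (anyNA(js) || any(js < 0)) stop("`j_tot` must be non-negative integers", call. = FALSE)
  j_max <- max(js, 0L)
  chain <- break_chain_core(model, j_max)

  rows <- lapply(js, function(j) {
    comps <- enumerate_compositions(j, model$events)
    acc <- 0
    for (i in seq_len(nrow(comps))) {
      if (comps$weight[i] == 0) next
      acc <- acc + comps$weight[i] *
        compose_stats(chain, model$fates, model$mode,
                      comps$j_a[i], comps$j_b[i], comps$j_c[i])
    }
    acc
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  out <- dplyr::mutate(out, j_tot = js, .before = 1)
  dplyr::mutate(
    out,
    frac_complex_ssb = ifelse(.data$e_ssb_lesions > 0,
                              (.data$e_ssb_lesions - .data$e_ssb_s) / .data$e_ssb_lesions,
                              NA_real_),
    frac_complex_dsb = ifelse(.data$e_dsb_lesions > 0,
                              (.data$e_dsb_plus + .data$e_dsb_pp) / .data$e_dsb_lesions,
                              NA_real_),
    dsb_to_ssb = ifelse(.data$e_ssb_lesions > 0,
                        .data$e_dsb_lesions / .data$e_ssb_lesions, NA_real_),
    bd_to_ssb = ifelse(.data$e_ssb_lesions > 0,
                       .data$e_bd / .data$e_ssb_lesions, NA_real_)
  )
}

#' Marginal damage probabilities at a given event number
#'
#' Convenience wrapper around [damage_probability_table()] for one or a few
#' values of `j_tot`.
#'
#' @inheritParams damage_probability_table
#' @return See [damage_probability_table()].
#' @export
damage_probabilities <- function(model, j_tot) {
  damage_probability_table(model, j_tot = j_tot)
}

#' Marginal statistics of a resolved lesion spectrum
#'
#' Computes the same marginals as one cell of [damage_probability_table()]
#' directly from a lesion spectrum, by full state summation. Used as the
#' slow reference for the factorized table.
#'
#' @param spectrum A `lesion_spectrum` tibble.
#' @return A named numeric vector of probabilities and expectations.
#' @export
spectrum_marginals <- function(spectrum) {
  sp <- tibble_to_lspec(spectrum)
  base <- lspec_stats_base(sp)
  bd_vals <- seq_along(base$bd_dist) - 1L
  at <- function(k) if (k + 1L > length(base$bd_dist)) 0 else base$bd_dist[k + 1L]
  c(base$core,
    p_dsb_no_bd = base$p_dsb_bd0,
    p_dsb_s_no_bd = base$p_dsb_s_bd0,
    p_dsb_plus_no_bd = base$p_dsb_plus_bd0,
    p_dsb_pp_no_bd = base$p_dsb_pp_bd0,
    p_bd_1 = at(1L), p_bd_2 = at(2L), p_bd_3 = at(3L),
    p_bd_gt3 = sum(base$bd_dist[bd_vals > 3]),
    e_bd = base$e_bd0)
}

#' DSB probability with and without base-damage co-location
#'
#' Returns, per `j_tot`: the probability of at least one DSB under the full
#' parameter set (`p_dsb`); the estimator of DSBs without co-located base
#' damage obtained by switching the OH-radical base-damage channel off
#' (`r2 = 0`, its weight absorbed by the inert fate) and taking the
#' zero-base-damage DSB marginal of that variant (`p_dsb_r2_zero`; base
#' damage then comes only from direct base ionizations); and the direct
#' marginal probability of at least one DSB together with zero base damages
#' under the full parameter set (`p_dsb_no_bd`).
#'
#' @inheritParams damage_probability_table
#' @return A tibble with columns `j_tot`, `p_dsb`, `p_dsb_r2_zero`,
#'   `p_dsb_no_bd`.
#' @examples
#' dsb_bd_colocation(damage_model(), j_tot = c(2, 6, 12))
#' @export
dsb_bd_colocation <- function(model, j_tot) {
  stopifnot(inherits(model, "damage_model"))
  full <- damage_probability_table(model, j_tot)
  model0 <- model
  model0$fates <- radical_fates(r1 = model$fates$r1, r2 = 0,
                                r3 = model$fates$r3 + model$fates$r2)
  off <- damage_probability_table(model0, j_tot)
  tibble::tibble(j_tot = full$j_tot,
                 p_dsb = full$p_dsb_any,
                 p_dsb_r2_zero = off$p_dsb_no_bd,
                 p_dsb_no_bd = full$p_dsb_no_bd)
}

#' Lesion-class distribution conditional on the number of induced breaks
#'
#' Probabilities of the strand-break lesion classes given that `n_breaks`
#' strand breaks were induced in the segment (regardless of whether each came
#' from direct ionization or from a converted radical). This is the quantity
#' whose complexity structure drives the qualitative behaviour of the model:
#' the dominance of highly complex DSBs once the clustering ladder collapses
#' (`q0 ~ 0`), the rise of the DSB:SSB ratio above 1, and the disappearance
#' of isolated SSBs at large break numbers.
#'
#' @param model A [damage_model()].
#' @param n_breaks Integer vector of induced break numbers (>= 0).
#' @param q0_indexing `"per_order"` (default): the whole `n`-break expansion
#'   uses the single ladder value `q0(n)`, the structure of the closed-form
#'   order-`n` expansions; `"per_step"`: the k-th break uses `q0(k)`
#'   incrementally, as in [resolve_composition()].
#' @return A tibble with `n_breaks`, the break-class probability and
#'   expectation columns of [damage_probability_table()], and
#'   `frac_complex_ssb`, `frac_complex_dsb`, `dsb_to_ssb`.
#' @examples
#' damage_vs_breaks(damage_model(), n_breaks = 2:8)
#' @export
damage_vs_breaks <- function(model, n_breaks = 1:10,
                             q0_indexing = c("per_order", "per_step")) {
  stopifnot(inherits(model, "damage_model"))
  q0_indexing <- match.arg(q0_indexing)
  ns <- sort(unique(as.integer(n_breaks)))
  if (anyNA(ns) || any(ns < 0)) stop("`n_breaks` must be non-negative integers", call. = FALSE)
  geom <- model$geometry
  rows <- if (q0_indexing == "per_step") {
    chain <- break_chain_core(model, max(ns, 0L))
    lapply(ns, function(n) chain[n + 1L, ])
  } else {
    lapply(ns, function(n) {
      gn <- cluster_geometry(n_bp = geom$n_bp, window_bp = geom$window_bp,
                             q0_constant = q0_of(geom, max(n, 1L)))
      sp <- lspec_empty()
      for (i in seq_len(n)) sp <- lspec_add_break(sp, gn, mode = model$mode)
      lspec_stats_base(sp)$core
    })
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  out <- dplyr::mutate(out, n_breaks = ns, .before = 1)
  dplyr::mutate(
    out,
    frac_complex_ssb = ifelse(.data$e_ssb_lesions > 0,
                              (.data$e_ssb_lesions - .data$e_ssb_s) / .data$e_ssb_lesions,
                              NA_real_),
    frac_complex_dsb = ifelse(.data$e_dsb_lesions > 0,
                              (.data$e_dsb_plus + .data$e_dsb_pp) / .data$e_dsb_lesions,
                              NA_real_),
    dsb_to_ssb = ifelse(.data$e_ssb_lesions > 0,
                        .data$e_dsb_lesions / .data$e_ssb_lesions, Inf)
  )
}
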