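# Lesion-state bookkeeping.
#
# A lesion state is a multiset of lesions plus a base-damage count:
#   ssb_s    isolated simple SSBs
#   ssb_plus complex SSBs (2 same-strand breaks within the window)
#   ssb_pp   complex SSBs with 3 breaks
#   ssb_ppp  complex SSBs with >= 4 breaks (folded into ssb_pp on report)
#   dsb_s    simple DSBs (2 opposite-strand breaks)
#   dsb_plus DSBs with 3 breaks
#   dsb_pp   DSBs with >= 4 breaks
#   bd       base damages
# plus `n_breaks`, the number of strand breaks placed so far (needed because
# the absorbing classes ssb_ppp/dsb_pp hide their break count, while the
# clustering ladder q0(k) is indexed by it).
#
# Internally a spectrum is a list(counts = numeric matrix, prob = numeric);
# user-facing functions exchange tibbles of class "lesion_spectrum".

.les_cols <- c("ssb_s", "ssb_plus", "ssb_pp", "ssb_ppp",
               "dsb_s", "dsb_plus", "dsb_pp")
.state_cols <- c(.les_cols, "bd", "n_breaks")

# upgrade outcomes when a new break attaches to a lesion of each class:
# same-strand / opposite-strand attachment is equally probable
.trans_exact <- list(
  ssb_s    = c("ssb_plus", "dsb_s"),
  ssb_plus = c("ssb_pp", "dsb_plus"),
  ssb_pp   = c("ssb_ppp", "dsb_pp"),
  ssb_ppp  = c("ssb_ppp", "dsb_pp"),
  dsb_s    = "dsb_plus",
  dsb_plus = "dsb_pp",
  dsb_pp   = "dsb_pp"
)
# high-order truncation: attachment weight beyond the q1^3 tier is tallied
# along the DSB route only
.trans_dsb_route <- list(
  ssb_s    = "dsb_s",
  ssb_plus = "dsb_plus",
  ssb_pp   = "dsb_pp",
  ssb_ppp  = "dsb_pp",
  dsb_s    = "dsb_plus",
  dsb_plus = "dsb_pp",
  dsb_pp   = "dsb_pp"
)

lspec_empty <- function() {
  m <- matrix(0, nrow = 1L, ncol = length(.state_cols),
              dimnames = list(NULL, .state_cols))
  list(counts = m, prob = 1)
}

# merge duplicate states; drop states below a negligible probability
lspec_aggregate <- function(M, p, prune = 1e-16) {
  key <- do.call(paste, c(lapply(seq_len(ncol(M)), function(j) M[, j]),
                          sep = ","))
  ps <- rowsum(p, key)
  first <- !duplicated(key)
  Mu <- M[first, , drop = FALSE]
  Mu <- Mu[match(rownames(ps), key[first]), , drop = FALSE]
  p <- as.numeric(ps)
  keep <- p > prune
  list(counts = Mu[keep, , drop = FALSE], prob = p[keep])
}

# Action of one strand-break addition (the shared core of the A-operator and
# of the SSB branch of the B-operator): with probability q0(k) the break
# starts a new isolated lesion; with probability 2 q1(k) it joins an existing
# lesion, each lesion equally likely, same/opposite strand equally likely.
lspec_add_break <- function(sp, geom, k = NULL, mode = "exact") {
  M <- sp$counts
  p <- sp$prob
  S <- nrow(M)
  if (S == 0L) return(sp)
  nles <- rowSums(M[, .les_cols, drop = FALSE])
  nb <- M[, "n_breaks"]
  kk <- if (is.null(k)) nb + 1 else rep(as.numeric(k), S)
  q0k <- q0_of(geom, kk)
  q1k <- (1 - q0k) / 2
  truncate_tier <- mode == "paper_approx" & (nb - nles) >= 3

  Ms <- list(); ps <- list(); n_out <- 0L
  push <- function(Mi, pi) {
    n_out <<- n_out + 1L
    Ms[[n_out]] <<- Mi
    ps[[n_out]] <<- pi
  }

  w0 <- ifelse(nles == 0, 1, q0k)
  idx <- which(w0 > 0)
  if (length(idx)) {
    Mi <- M[idx, , drop = FALSE]
    Mi[, "ssb_s"] <- Mi[, "ssb_s"] + 1
    Mi[, "n_breaks"] <- Mi[, "n_breaks"] + 1
    push(Mi, p[idx] * w0[idx])
  }

  for (grp in c(FALSE, TRUE)) {
    trans <- if (grp) .trans_dsb_route else .trans_exact
    for (cat in .les_cols) {
      idx <- which(M[, cat] > 0 & nles > 0 & q1k > 0 & truncate_tier == grp)
      if (!length(idx)) next
      outs <- trans[[cat]]
      w <- 2 * q1k[idx] * M[idx, cat] / nles[idx] / length(outs)
      for (out in outs) {
        Mi <- M[idx, , drop = FALSE]
        if (out != cat) {
          Mi[, cat] <- Mi[, cat] - 1
          Mi[, out] <- Mi[, out] + 1
        }
        Mi[, "n_breaks"] <- Mi[, "n_breaks"] + 1
        push(Mi, p[idx] * w)
      }
    }
  }
  lspec_aggregate(do.call(rbind, Ms), unlist(ps, use.names = FALSE))
}

# B-operator: r1 -> strand break (as add_break), r2 -> base damage,
# r3 -> nothing. In paper_approx mode radical break terms are kept only to
# order r1^2: a state that already holds two radical-converted breaks sends
# further r1 weight to the inert branch, so products of three or more break
# conversions are rerouted rather than propagated.
lspec_b_step <- function(sp, geom, fates, mode = "exact", base_breaks = NULL) {
  r1 <- fates$r1; r2 <- fates$r2; r3 <- fates$r3
  if (mode == "paper_approx") {
    if (is.null(base_breaks)) base_breaks <- min(sp$counts[, "n_breaks"])
    capped <- sp$counts[, "n_breaks"] - base_breaks >= 2
  } else {
    capped <- rep(FALSE, nrow(sp$counts))
  }
  Ms <- list(); ps <- list(); i <- 0L
  if (r1 > 0 && any(!capped)) {
    sub <- list(counts = sp$counts[!capped, , drop = FALSE],
                prob = sp$prob[!capped])
    s1 <- lspec_add_break(sub, geom, k = NULL, mode = mode)
    i <- i + 1L; Ms[[i]] <- s1$counts; ps[[i]] <- s1$prob * r1
  }
  if (r2 > 0) {
    M2 <- sp$counts
    M2[, "bd"] <- M2[, "bd"] + 1
    i <- i + 1L; Ms[[i]] <- M2; ps[[i]] <- sp$prob * r2
  }
  r3_eff <- r3 + r1 * capped
  if (any(r3_eff > 0)) {
    i <- i + 1L; Ms[[i]] <- sp$counts; ps[[i]] <- sp$prob * r3_eff
  }
  lspec_aggregate(do.call(rbind, Ms), unlist(ps, use.names = FALSE))
}

lspec_c_step <- function(sp, n = 1L) {
  M <- sp$counts
  M[, "bd"] <- M[, "bd"] + n
  list(counts = M, prob = sp$prob)
}

lspec_resolve <- function(j_a, j_b, j_c, geom, fates, mode) {
  sp <- lspec_empty()
  for (i in seq_len(j_a)) sp <- lspec_add_break(sp, geom, mode = mode)
  for (i in seq_len(j_b)) sp <- lspec_b_step(sp, geom, fates, mode = mode,
                                             base_breaks = j_a)
  if (j_c > 0) sp <- lspec_c_step(sp, j_c)
  sp
}

lspec_to_tibble <- function(sp) {
  tb <- tibble::as_tibble(as.data.frame(sp$counts))
  tb$prob <- sp$prob
  tb <- dplyr::arrange(tb, dplyr::across(dplyr::all_of(.state_cols)))
  class(tb) <- c("lesion_spectrum", class(tb))
  tb
}

tibble_to_lspec <- function(tb) {
  tb <- tibble::as_tibble(tb)
  for (cl in c(.les_cols, "bd")) {
    if (is.null(tb[[cl]])) tb[[cl]] <- 0
  }
  if (is.null(tb$prob)) stop("a lesion spectrum needs a `prob` column", call. = FALSE)
  if (is.null(tb$n_breaks)) {
    # minimum consistent break count (absorbing classes may hide extra breaks)
    tb$n_breaks <- tb$ssb_s + 2 * tb$ssb_plus + 3 * tb$ssb_pp +
      4 * tb$ssb_ppp + 2 * tb$dsb_s + 3 * tb$dsb_plus + 4 * tb$dsb_pp
  }
  list(counts = as.matrix(tb[, .state_cols]), prob = tb$prob)
}

#' Apply one A-operator step to a lesion spectrum
#'
#' Adds one strand break from a direct sugar-phosphate ionization. Each state
#' branches: with probability `q0(k)` the break starts a new isolated SSB;
#' with total probability `2 q1(k)` it joins one of the existing lesions (all
#' equally likely), landing on the same or the opposite strand with equal
#' probability, which upgrades that lesion (for example an isolated SSB
#' becomes a same-strand complex SSB or a simple DSB; a simple DSB becomes a
#' DSB+).
#'
#' @param spectrum A lesion spectrum tibble (as returned by
#'   [resolve_composition()], or any tibble with lesion-count columns and
#'   `prob`). An empty spectrum is `lesion_spectrum_empty()`.
#' @param geom A [cluster_geometry()].
#' @param k Index of the break being added (the k-th SSB); default `NULL`
#'   uses each state's own break count + 1, which is what
#'   [resolve_composition()] does.
#' @param mode `"exact"` or `"paper_approx"`.
#' @return A normalized `lesion_spectrum` tibble.
#' @examples
#' lesion_spectrum_empty() |>
#'   apply_a_step(cluster_geometry()) |>
#'   apply_a_step(cluster_geometry())
#' @export
apply_a_step <- function(spectrum, geom, k = NULL, mode = c("exact", "paper_approx")) {
  mode <- match.arg(mode)
  stopifnot(inherits(geom, "cluster_geometry"))
  lspec_to_tibble(lspec_add_break(tibble_to_lspec(spectrum), geom, k = k, mode = mode))
}

#' Apply one B-operator step (OH-radical attack) to a lesion spectrum
#'
#' With probability `r1` the radical converts to a strand break (then behaves
#' exactly as [apply_a_step()]); with probability `r2` it produces one base
#' damage; with probability `r3` nothing happens.
#'
#' @inheritParams apply_a_step
#' @param fates A [radical_fates()].
#' @param base_breaks Number of strand breaks in the spectrum that did not
#'   come from radical conversions; in `paper_approx` mode a state stops
#'   converting radicals to breaks once it holds two radical breaks (terms
#'   beyond order `r1^2` are rerouted to the inert branch). Defaults to the
#'   smallest break count across states, which is exact for spectra resolved
#'   from a fixed composition.
#' @return A normalized `lesion_spectrum` tibble.
#' @export
apply_b_step <- function(spectrum, geom, fates, base_breaks = NULL,
                         mode = c("exact", "paper_approx")) {
  mode <- match.arg(mode)
  stopifnot(inherits(geom, "cluster_geometry"), inherits(fates, "radical_fates"))
  lspec_to_tibble(lspec_b_step(tibble_to_lspec(spectrum), geom, fates,
                               mode = mode, base_breaks = base_breaks))
}

#' Apply one C-operator step (direct base ionization) to a lesion spectrum
#'
#' Increments every state's base-damage count by one; probabilities are
#' unchanged.
#'
#' @inheritParams apply_a_step
#' @return A `lesion_spectrum` tibble.
#' @export
apply_c_step <- function(spectrum) {
  lspec_to_tibble(lspec_c_step(tibble_to_lspec(spectrum)))
}

#' The empty lesion spectrum
#'
#' @return A one-state `lesion_spectrum` tibble: no lesions, probability 1.
#' @export
lesion_spectrum_empty <- function() lspec_to_tibble(lspec_empty())

#' Resolve an event composition into a lesion-class distribution
#'
#' Applies `j_a` A-steps, `j_b` B-steps and `j_c` C-steps to the empty state
#' (the order of heterogeneous factors does not change the result; D events
#' are inert) and returns the probability distribution over lesion states.
#'
#' @param model A [damage_model()], or `NULL` to pass `geom`/`fates` directly.
#' @param composition Numeric vector `c(j_a, j_b, j_c, j_d)` (or a one-row
#'   data frame with those columns).
#' @param geom,fates,mode Overrides for the corresponding model components.
#' @return A normalized `lesion_spectrum` tibble with one row per lesion
#'   state, its class counts, `bd`, bookkeeping column `n_breaks`, and `prob`.
#' @examples
#' resolve_composition(damage_model(), c(2, 0, 0, 0))
#' @export
resolve_composition <- function(model = NULL, composition,
                                geom = model$geometry, fates = model$fates,
                                mode = model$mode %||% "exact") {
  if (is.data.frame(composition)) {
    composition <- as.numeric(composition[1, c("j_a", "j_b", "j_c", "j_d")])
  }
  if (length(composition) < 3L || anyNA(composition[1:3]) ||
      any(composition < 0) || any(composition != floor(composition))) {
    stop("`composition` must be non-negative integer counts (j_a, j_b, j_c, j_d)",
         call. = FALSE)
  }
  stopifnot(inherits(geom, "cluster_geometry"), inherits(fates, "radical_fates"))
  sp <- lspec_resolve(composition[1], composition[2], composition[3],
                      geom, fates, mode)
  out <- lspec_to_tibble(sp)
  attr(out, "composition") <- composition
  attr(out, "mode") <- mode
  out
}

#' Fold a lesion spectrum for reporting
#'
#' Aggregates over the bookkeeping break count and folds the >=4-break
#' same-strand class (`ssb_ppp`) into `ssb_pp`, the grouping used in reported
#' damage spectra.
#'
#' @param spectrum A `lesion_spectrum` tibble.
#' @return A tibble with columns `ssb_s`, `ssb_plus`, `ssb_pp`, `dsb_s`,
#'   `dsb_plus`, `dsb_pp`, `bd`, `prob`.
#' @export
fold_lesion_spectrum <- function(spectrum) {
  tb <- tibble::as_tibble(spectrum)
  tb$ssb_pp <- tb$ssb_pp + tb$ssb_ppp
  tb |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("ssb_s", "ssb_plus", "ssb_pp", "dsb_s", "dsb_plus", "dsb_pp", "bd")))) |>
    dplyr::summarise(prob = sum(.data$prob), .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::everything()))
}
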