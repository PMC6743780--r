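# Simulated listener survey: group-specific linear dependence of emotion
# ratings on tonality, rhythm and familiarity, discretized to the 0-4
# instrument.

#' Default per-group rating-model coefficients
#'
#' Coefficient table for the two built-in scenarios. In
#' `"cross_cultural"`, enculturated ("E") listeners weight tonality
#' heavily and rhythm lightly, non-enculturated ("NE") listeners the
#' reverse; signs follow the valence conventions of the tonality ratio
#' (higher minor-interval occupancy raises sad/tensed/longing/angry and
#' lowers happy/calm/romantic/devotional) and of the pulsed gat mode. In
#' `"null"` both groups share one identical coefficient set and
#' familiarity distribution, so every between-group null hypothesis is
#' true by construction.
#'
#' @param scenario `"cross_cultural"` or `"null"`.
#' @return [tibble::tibble()] with columns `group`, `emotion`,
#'   `intercept`, `b_tonality`, `b_rhythm`, `b_familiarity`.
#' @export
default_coefficients <- function(scenario = c("cross_cultural", "null")) {
  scenario <- match.arg(scenario)
  # Intercepts and slopes are laid out so that each corner of the
  # (tonality, rhythm) design space has one clearly dominant emotion
  # (calm: low-m/M alaap; happy: low-m/M gat; sad: high-m/M alaap;
  # tensed: high-m/M gat), as ragas do: this keeps modal labels stable
  # across independent samples from one process.
  e <- tibble::tribble(
    ~emotion,     ~intercept, ~b_tonality, ~b_rhythm, ~b_familiarity,
    "happy",      2.5,        -1.40,        0.70,     0.05,
    "romantic",   2.0,        -1.20,        0.30,     0.05,
    "devotional", 2.2,        -1.00,       -0.60,     0.05,
    "calm",       2.9,        -1.50,       -0.50,     0.05,
    "angry",      0.4,         1.20,        0.50,     0.05,
    "longing",    0.8,         1.20,        0.20,     0.05,
    "tensed",     0.7,         1.50,        0.60,     0.05,
    "sad",        1.0,         1.50,       -0.50,     0.05)
  ne <- tibble::tribble(
    ~emotion,     ~intercept, ~b_tonality, ~b_rhythm, ~b_familiarity,
    "happy",      2.5,        -0.30,        1.20,     0.05,
    "romantic",   2.0,        -0.25,        0.90,     0.05,
    "devotional", 2.2,        -0.30,       -1.00,     0.05,
    "calm",       2.9,        -0.40,       -1.20,     0.04,
    "angry",      0.5,         0.25,        0.90,     0.05,
    "longing",    0.8,         0.30,        0.80,     0.04,
    "tensed",     0.8,         0.35,        1.20,     0.05,
    "sad",        1.1,         0.40,       -1.00,     0.04)
  if (scenario == "null") ne <- e
  dplyr::bind_rows(
    dplyr::mutate(e, group = "E", .before = 1),
    dplyr::mutate(ne, group = "NE", .before = 1))
}

#' Parameters for the rating simulator
#'
#' @param coefficients per-group, per-emotion linear coefficients (see
#'   [default_coefficients()]); must cover both groups and all eight
#'   emotions.
#' @param noise_sd rating noise standard deviation, in rating units,
#'   applied before rounding (default 0.8).
#' @param familiarity data frame with columns `group`, `mean`, `sd`:
#'   the per-group familiarity-score distribution on the 0-4 scale
#'   (defaults 2.86 (1.09) for E and 1.99 (1.02) for NE; in the `"null"`
#'   scenario both groups share the E distribution).
#' @param n_participants named vector `c(E = ..., NE = ...)` (defaults
#'   143 and 112, the survey group sizes).
#' @param completion_probs probabilities that a participant completes 2,
#'   3 or all 4 survey blocks (default `c(0.30, 0.15, 0.55)`): the survey
#'   allowed opting out after two blocks, which is what makes per-excerpt
#'   rater sets (and hence mean familiarity) vary across excerpts. Use
#'   `c(0, 0, 1)` for a fully crossed table.
#' @return object of class `rating_sim_params`.
#' @export
rating_sim_params <- function(coefficients = default_coefficients(),
                              noise_sd = 0.8,
                              familiarity = NULL,
                              n_participants = c(E = 143, NE = 112),
                              completion_probs = c(0.30, 0.15, 0.55)) {
  if (is.null(familiarity))
    familiarity <- data.frame(group = GROUPS, mean = c(2.86, 1.99),
                              sd = c(1.09, 1.02))
  stopifnot(is.data.frame(coefficients),
            all(c("group", "emotion", "intercept", "b_tonality", "b_rhythm",
                  "b_familiarity") %in% names(coefficients)),
            is_scalar_number(noise_sd), noise_sd >= 0,
            is.data.frame(familiarity),
            all(GROUPS %in% familiarity$group),
            all(GROUPS %in% names(n_participants)))
  missing <- setdiff(as.vector(outer(GROUPS, EMOTIONS, paste)),
                     paste(coefficients$group, coefficients$emotion))
  if (length(missing))
    stop("coefficients missing for: ", paste(missing, collapse = ", "))
  if (any(n_participants < 1))
    stop("n_participants must be at least 1 per group")
  stopifnot(is.numeric(completion_probs), length(completion_probs) == 3L,
            all(completion_probs >= 0), sum(completion_probs) > 0)
  structure(list(coefficients = coefficients, noise_sd = noise_sd,
                 familiarity = familiarity,
                 n_participants = n_participants,
                 completion_probs = completion_probs / sum(completion_probs)),
            class = "rating_sim_params")
}

#' Convenience constructor for the two built-in scenarios
#'
#' @param scenario `"cross_cultural"` or `"null"`.
#' @param ... overrides passed to [rating_sim_params()].
#' @return a `rating_sim_params`.
#' @export
default_sim_params <- function(scenario = c("cross_cultural", "null"), ...) {
  scenario <- match.arg(scenario)
  args <- list(coefficients = default_coefficients(scenario), ...)
  if (scenario == "null" && is.null(args$familiarity))
    args$familiarity <- data.frame(group = GROUPS, mean = c(2.86, 2.86),
                                   sd = c(1.09, 1.09))
  do.call(rating_sim_params, args)
}

#' Simulate a long-format rating table
#'
#' One row per participant x rated excerpt x emotion. Each participant
#' draws a familiarity score from their group's distribution (rounded and
#' clipped to the 0-4 instrument) and completes 2, 3 or 4 of the survey's
#' alternating alaap/gat blocks (six ragas per block, starting mode
#' counterbalanced); each rating is the group/emotion linear predictor
#' evaluated at the excerpt's tonality and rhythm plus Gaussian noise,
#' rounded and clipped to the integer 0-4 scale. Deterministic per seed.
#'
#' @param params a [rating_sim_params()].
#' @param stimuli data frame with columns `raga`, `mode` ("alaap"/"gat")
#'   and `tonality` (one row per excerpt, at least one).
#' @param seed integer seed.
#' @return [tibble::tibble()] with columns `participant_id`, `group`,
#'   `familiarity`, `raga`, `mode`, `emotion`, `rating`.
#' @export
simulate_ratings <- function(params, stimuli, seed) {
  stopifnot(inherits(params, "rating_sim_params"),
            is.data.frame(stimuli),
            all(c("raga", "mode", "tonality") %in% names(stimuli)))
  if (nrow(stimuli) < 1L) stop("need at least one stimulus")
  if (!all(stimuli$mode %in% c("alaap", "gat")))
    stop("stimulus mode must be 'alaap' or 'gat'")
  # Survey block structure: ragas split into two halves, presented in four
  # alternating alaap/gat blocks; the half x mode cell's block index
  # depends on whether the participant's first block is alaap or gat.
  ragas <- unique(stimuli$raga)
  half <- rep(1:2, length.out = length(ragas))[match(stimuli$raga, ragas)]
  is_gat <- stimuli$mode == "gat"
  block_if_alaap_first <- ifelse(!is_gat, ifelse(half == 1, 1L, 3L),
                                 ifelse(half == 2, 2L, 4L))
  block_if_gat_first <- ifelse(is_gat, ifelse(half == 1, 1L, 3L),
                               ifelse(half == 2, 2L, 4L))
  with_seed(seed, {
    tabs <- lapply(GROUPS, function(g) {
      n <- params$n_participants[[g]]
      fam_d <- params$familiarity[params$familiarity$group == g, ][1L, ]
      fam <- pmin(4, pmax(0, round(rnorm(n, fam_d$mean, fam_d$sd))))
      ids <- sprintf("%s%03d", g, seq_len(n))
      n_blocks <- sample(2:4, n, replace = TRUE,
                         prob = params$completion_probs)
      gat_first <- rep(c(FALSE, TRUE), length.out = n)
      co <- params$coefficients[params$coefficients$group == g, ]
      grid <- expand.grid(participant = seq_len(n),
                          excerpt = seq_len(nrow(stimuli)),
                          emotion = EMOTIONS,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      blk <- ifelse(gat_first[grid$participant],
                    block_if_gat_first[grid$excerpt],
                    block_if_alaap_first[grid$excerpt])
      grid <- grid[blk <= n_blocks[grid$participant], , drop = FALSE]
      co_idx <- match(grid$emotion, co$emotion)
      mu <- co$intercept[co_idx] +
        co$b_tonality[co_idx] * stimuli$tonality[grid$excerpt] +
        co$b_rhythm[co_idx] * as.integer(stimuli$mode[grid$excerpt] == "gat") +
        co$b_familiarity[co_idx] * fam[grid$participant]
      noise <- if (params$noise_sd > 0)
        rnorm(nrow(grid), 0, params$noise_sd) else 0
      tibble::tibble(
        participant_id = ids[grid$participant],
        group = g,
        familiarity = fam[grid$participant],
        raga = stimuli$raga[grid$excerpt],
        mode = stimuli$mode[grid$excerpt],
        emotion = grid$emotion,
        rating = as.integer(pmin(4, pmax(0, round(mu + noise)))))
    })
    dplyr::bind_rows(tabs)
  })
}
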