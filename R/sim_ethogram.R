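#' Simulate a per-second behaviour sequence for one bird
#'
#' Generates a 1-s resolution ethogram with central-place structure:
#' alternating colony-attendance (rest_land) and at-sea blocks. Within each
#' at-sea block behaviour follows a semi-Markov chain over flapping, gliding
#' and surface resting with exponential dwell times; a flight segment may end
#' in a plunge dive and a surface-rest segment in a duck dive, so dives occur
#' only at sea and each dive type is preceded by its defining behaviour. Each
#' trip begins and ends with flapping (the commute).
#'
#' Per-bird heterogeneity multiplies the at-sea dwell means by lognormal
#' factors so birds differ in their activity budgets, as real cohorts do.
#'
#' @param config A [sim_config()].
#' @param bird_id Integer bird identifier (selects the RNG stream).
#' @return A list of class `sim_bird` with elements `ethogram` (data.table:
#'   `second` 0-based index, `behaviour` factor over [behaviour_levels()])
#'   and `truth` (list: `bird_id`, `true_T_i` hours per behaviour, `true_EE`
#'   kJ = sum of C_i * T_i, dive counts).
#' @export
#' @examples
#' bird <- simulate_ethogram(sim_config(deployment_h = 6), bird_id = 1)
#' table(bird$ethogram$behaviour)
#' bird$truth$true_EE
simulate_ethogram <- function(config, bird_id = 1L) {
  validate_sim_config(config)
  n_sec <- round(config$deployment_h * 3600)
  if (n_sec < min(config$behaviour_dwell))
    stop("deployment shorter than the smallest mean dwell time")
  set.seed(sim_seed(config, bird_id, 1L))

  dwell <- config$behaviour_dwell
  # per-bird heterogeneity on at-sea dwell means
  het <- config$bird_heterogeneity
  if (het > 0) {
    mult <- stats::rlnorm(3, meanlog = -het^2 / 2, sdlog = het)
    dwell[c("flapping", "gliding", "rest_sea")] <-
      dwell[c("flapping", "gliding", "rest_sea")] * mult
  }

  labels <- character(n_sec)
  t_used <- 0L

  draw_dwell <- function(mean_s) max(1L, as.integer(round(stats::rexp(1, 1 / mean_s))))

  append_seg <- function(beh, len) {
    len <- min(len, n_sec - t_used)
    if (len > 0L) {
      labels[(t_used + 1L):(t_used + len)] <<- beh
      t_used <<- t_used + len
    }
  }

  sea_states <- names(config$sea_state_prob)
  at_sea_possible <- config$sea_block_h > 0

  on_land <- TRUE
  while (t_used < n_sec) {
    if (on_land || !at_sea_possible) {
      append_seg("rest_land", draw_dwell(config$colony_block_h * 3600))
      on_land <- FALSE
      next
    }
    # one at-sea block; a commute-home flight is reserved at its end so the
    # bird always flies back to the colony
    block_len <- draw_dwell(config$sea_block_h * 3600)
    block_end <- min(n_sec, t_used + block_len)
    # commutes must carry the bird well clear of the colony (1.5x the 0.5-km
    # colony radius) before any other at-sea behaviour starts
    commute_min <- ceiling(0.75 / config$trip_speed * 3600)
    home_len <- min(max(draw_dwell(dwell["flapping"]), commute_min),
                    block_end - t_used)
    mid_end <- block_end - home_len
    first_seg <- TRUE
    prev <- NA_character_
    while (t_used < mid_end) {
      if (first_seg) {
        st <- "flapping"      # commute out
        append_seg(st, min(max(draw_dwell(dwell[st]), commute_min),
                           mid_end - t_used))
        prev <- st
        first_seg <- FALSE
        next
      } else {
        repeat {
          st <- sample(sea_states, 1, prob = config$sea_state_prob)
          if (is.na(prev) || st != prev) break
        }
      }
      append_seg(st, min(draw_dwell(dwell[st]), mid_end - t_used))
      prev <- st
      # possible dive terminating the segment; submersions shorter than ~3 s
      # are not physically plausible for this forager, so dive dwells are
      # floored there
      if (t_used < mid_end - 1L) {
        if (st %in% c("flapping", "gliding") && stats::runif(1) < config$p_plunge) {
          append_seg("plunge_dive", min(max(3L, draw_dwell(dwell["plunge_dive"])),
                                        mid_end - t_used))
          prev <- "plunge_dive"
        } else if (st == "rest_sea" && stats::runif(1) < config$p_duck) {
          append_seg("duck_dive", min(max(3L, draw_dwell(dwell["duck_dive"])),
                                      mid_end - t_used))
          prev <- "duck_dive"
        }
      }
    }
    append_seg("flapping", home_len)   # commute home
    on_land <- TRUE
  }

  behaviour <- factor(labels, levels = BEHAVIOURS)
  eth <- data.table::data.table(second = seq_len(n_sec) - 1L, behaviour = behaviour)

  counts <- tabulate(behaviour, nbins = length(BEHAVIOURS))
  names(counts) <- BEHAVIOURS
  true_T_i <- counts / 3600
  true_EE <- sum(config$true_coefficients[BEHAVIOURS] * true_T_i[BEHAVIOURS])
  rl <- rle(labels)
  truth <- list(
    bird_id = bird_id,
    true_T_i = true_T_i,
    true_EE = true_EE,
    n_plunge = sum(rl$values == "plunge_dive"),
    n_duck = sum(rl$values == "duck_dive")
  )
  structure(list(ethogram = eth, truth = truth, config = config),
            class = "sim_bird")
}
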