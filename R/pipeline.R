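#' Run the full utilisation pipeline
#'
#' Convenience wrapper chaining cohort selection, episode construction and
#' treatment-free extraction over a dispensing record table.
#'
#' @param records Dispensing records data frame.
#' @param formulary A `formulary` object.
#' @param cohort_cfg A [cohort_config()].
#' @param episode_cfg An [episode_config()].
#' @return List with `cohort` (`ad_cohort`), `episodes` (`ad_episodes`)
#'   and `treatment_free` (data frame).
#' @export
run_pipeline <- function(records, formulary = default_formulary(),
                         cohort_cfg = cohort_config(),
                         episode_cfg = episode_config()) {
  cohort <- build_cohort(records, formulary, cohort_cfg)
  episodes <- build_episodes(records, cohort, formulary, episode_cfg)
  tf <- treatment_free_episodes(episodes)
  list(cohort = cohort, episodes = episodes, treatment_free = tf)
}
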