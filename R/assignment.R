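#' Assign the notification recipient for an encounter
#'
#' For outpatient echoes the assigned provider is always the ordering
#' provider.  For inpatient echoes a hierarchy applies: (1) the ordering
#' provider if they are a cardiologist, (2) the cardiologist managing the
#' patient's care, (3) the primary care provider, (4) the ordering provider.
#' The hierarchy always terminates, so no error is possible.
#'
#' @param encounter A list with `setting` (`"inpatient"`/`"outpatient"`),
#'   `ordering_provider`, `ordering_is_cardiologist` (flag), and optional
#'   `managing_cardiologist` and `primary_care_provider` (each a provider id
#'   or `NA`/`NULL` when absent).
#' @return The assigned provider (as supplied, typically an id).
#' @export
assign_provider <- function(encounter) {
  stopifnot(!is.null(encounter$ordering_provider),
            encounter$setting %in% c("inpatient", "outpatient"))
  if (encounter$setting == "outpatient") return(encounter$ordering_provider)
  present <- function(x) !is.null(x) && length(x) == 1 && !is.na(x)
  if (isTRUE(encounter$ordering_is_cardiologist))
    return(encounter$ordering_provider)
  if (present(encounter$managing_cardiologist))
    return(encounter$managing_cardiologist)
  if (present(encounter$primary_care_provider))
    return(encounter$primary_care_provider)
  encounter$ordering_provider
}

# Balanced 1:1 arm labels for n units, by seeded permutation: floor(n/2) of
# each arm, any odd remainder going to a randomly chosen arm.
.balanced_arms <- function(n) {
  if (n == 0) return(character(0))
  half <- n %/% 2
  arms <- c(rep("notification", half), rep("control", half))
  if (n %% 2 == 1)
    arms <- c(arms, sample(c("notification", "control"), 1))
  sample(arms)
}

#' First-tranche stratified provider randomization
#'
#' Randomizes providers with known historical echo volumes 1:1 into
#' notification and control arms within echo-volume strata nested in site.
#' Strata are quantile bins of `historical_echo_volume` within each site
#' (tertiles by default); within each stratum the allocation is exactly
#' balanced (imbalance at most 1 for odd strata) via a seeded permutation.
#'
#' @param providers Data frame with columns `provider_id`, `site`,
#'   `historical_echo_volume` (no missing values).
#' @param n_strata Number of volume strata per site (default 3).
#' @param seed Integer seed; assignments are reproducible from it.
#' @return Data frame `provider_id, site, stratum, tranche, arm, seed`.
#' @export
randomize_tranche1 <- function(providers, n_strata = 3, seed) {
  if (nrow(providers) == 0)
    return(data.frame(provider_id = character(0), site = character(0),
                      stratum = integer(0), tranche = integer(0),
                      arm = character(0), seed = integer(0)))
  stopifnot(all(c("provider_id", "site", "historical_echo_volume") %in%
                  names(providers)),
            !anyNA(providers$historical_echo_volume))
  set.seed(seed)
  out <- providers[, c("provider_id", "site")]
  out$stratum <- NA_integer_
  out$arm <- NA_character_
  for (s in unique(providers$site)) {
    idx <- which(providers$site == s)
    vol <- providers$historical_echo_volume[idx]
    k <- min(n_strata, length(unique(vol)))
    breaks <- unique(stats::quantile(vol, probs = seq(0, 1, length.out = k + 1)))
    stratum <- findInterval(vol, breaks, rightmost.closed = TRUE,
                            all.inside = TRUE)
    out$stratum[idx] <- stratum
    for (b in unique(stratum)) {
      members <- idx[stratum == b]
      out$arm[members] <- .balanced_arms(length(members))
    }
  }
  out$tranche <- 1L
  out$seed <- as.integer(seed)
  out[, c("provider_id", "site", "stratum", "tranche", "arm", "seed")]
}

#' Create a second-tranche site allocator
#'
#' Second-tranche providers (no historical echo volume) are randomized 1:1
#' upon ordering an echo for an eligible patient, via permuted blocks within
#' site so the running imbalance at a site never exceeds half a block.  The
#' allocator is a stateful object; once a provider is assigned, repeat
#' queries return the stored arm unchanged (arms are immutable for the study
#' duration).
#'
#' @param seed Integer seed; the block stream is reproducible from it.
#' @param block_size Even permuted-block size (default 4).
#' @return A `site_allocator` environment; query with [randomize_tranche2()].
#' @export
site_allocator <- function(seed, block_size = 4) {
  stopifnot(block_size %% 2 == 0, block_size >= 2)
  env <- new.env(parent = emptyenv())
  env$seed <- as.integer(seed)
  env$block_size <- as.integer(block_size)
  env$assigned <- list()     # provider_id -> arm
  env$queue <- character(0)  # remaining arms in the current block
  env$block_index <- 0L
  class(env) <- "site_allocator"
  env
}

#' Second-tranche provider randomization
#'
#' Assigns (or recalls) the arm of one provider at the site governed by
#' `state`.  A provider already assigned keeps their arm; a warning is issued
#' on such re-randomization attempts.
#'
#' @param provider_id Opaque provider identifier.
#' @param state A [site_allocator()].
#' @return `"notification"` or `"control"`.
#' @export
randomize_tranche2 <- function(provider_id, state) {
  stopifnot(inherits(state, "site_allocator"))
  pid <- as.character(provider_id)
  if (!is.null(state$assigned[[pid]])) {
    warning("provider ", pid, " already randomized; returning existing arm")
    return(state$assigned[[pid]])
  }
  if (length(state$queue) == 0) {
    state$block_index <- state$block_index + 1L
    # Independent, reproducible stream per block; the global RNG state is
    # left untouched.
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv()))
              rm(".Random.seed", envir = globalenv()))
    set.seed((state$seed + 7919L * state$block_index) %% .Machine$integer.max)
    half <- state$block_size %/% 2
    state$queue <- sample(c(rep("notification", half), rep("control", half)))
  }
  arm <- state$queue[1]
  state$queue <- state$queue[-1]
  state$assigned[[pid]] <- arm
  arm
}
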