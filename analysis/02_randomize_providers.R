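#!/usr/bin/env Rscript
# Demonstrates the two-tranche provider randomization on a synthetic roster:
# tranche 1 stratified by historical echo volume within site, tranche 2 by
# permuted blocks as providers order echoes for eligible patients.

suppressPackageStartupMessages(library(echotrial))
dir.create("results", showWarnings = FALSE)
set.seed(20260902)

sites <- sprintf("site%d", 1:5)
roster <- data.frame(
  provider_id = sprintf("prov%04d", 1:450),
  site = sample(sites, 450, replace = TRUE),
  historical_echo_volume = rpois(450, 120))

t1 <- randomize_tranche1(roster, n_strata = 3, seed = 11)
message("tranche 1: ", nrow(t1), " providers; arm balance by site/stratum:")
bal <- aggregate(arm ~ site + stratum, t1,
                 function(a) sum(a == "notification") - sum(a == "control"))
names(bal)[3] <- "imbalance"
print(bal[order(bal$site, bal$stratum), ], row.names = FALSE)
stopifnot(all(abs(bal$imbalance) <= 1))

# tranche 2: 150 late-joining providers trickle in per site
allocs <- lapply(seq_along(sites), function(i) site_allocator(seed = 100 + i))
names(allocs) <- sites
late <- data.frame(provider_id = sprintf("prov9%03d", 1:150),
                   site = sample(sites, 150, replace = TRUE))
late$arm <- vapply(seq_len(nrow(late)), function(i)
  randomize_tranche2(late$provider_id[i], allocs[[late$site[i]]]),
  character(1))
t2 <- data.frame(provider_id = late$provider_id, site = late$site,
                 stratum = NA_integer_, tranche = 2L, arm = late$arm,
                 seed = vapply(late$site, function(s) allocs[[s]]$seed,
                               integer(1)))
message("tranche 2: ", nrow(t2), " providers; per-site imbalance:")
print(tapply(t2$arm, t2$site,
             function(a) sum(a == "notification") - sum(a == "control")))

assignments <- rbind(t1, t2)
write.csv(assignments, "results/provider_assignments.csv", row.names = FALSE)
message("wrote results/provider_assignments.csv (",
        nrow(assignments), " rows)")
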