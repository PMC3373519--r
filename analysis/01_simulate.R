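#!/usr/bin/env Rscript
# Stage 1: generate every synthetic dataset the downstream stages read.
#
# The outline sample emulates the digitized external-naris material: 30
# closed tear-shaped outlines, 15 at the published intermediate
# length/width ratio (2.4, inside the diagnostic 1.85-2.85 band) and 15
# in the elongate class (3.2, above 2.85), with 2% smooth radial noise
# and randomized rotation/translation/scale/starting point.  The
# character matrix emulates a morphology-like discrete matrix evolved on
# a known tree; the range history and allometric sample likewise carry
# recorded truth.

suppressPackageStartupMessages(library(morphoclade))

seed <- 20260923
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

g <- gen_outlines(noise_sd = 0.02, jitter = TRUE, m_points = 128,
                  seed = seed)
write_outlines_csv(g$shapes, file.path(out, "outlines.csv"))
write.csv(g$truth, file.path(out, "outlines_truth.csv"), row.names = FALSE)
cat(sprintf("outlines: %d shapes in %d groups -> %s\n",
            length(g$shapes), length(unique(g$truth$group)),
            file.path(out, "outlines.csv")))

gm <- gen_matrix(n_taxa = 12, n_characters = 80, n_states = 3,
                 changes_per_char = 2, missing_fraction = 0.1,
                 seed = seed + 1)
write_nexus(gm$matrix, file.path(out, "matrix.nex"))
ape::write.tree(gm$tree, file.path(out, "true_tree.nwk"))
write.csv(gm$truth, file.path(out, "matrix_truth.csv"), row.names = FALSE)
cat(sprintf("matrix: %d taxa x %d characters (true tree written)\n",
            n_taxa(gm$matrix), n_characters(gm$matrix)))

h <- gen_ranges(n_taxa = 12, n_areas = 4, n_dispersals = 2,
                n_extinctions = 1, seed = seed + 2)
ape::write.tree(h$tree, file.path(out, "range_tree.nwk"))
write.csv(data.frame(taxon = names(h$ranges),
                     areas = vapply(h$ranges, paste, character(1),
                                    collapse = ";")),
          file.path(out, "ranges.csv"), row.names = FALSE)
write.csv(h$events, file.path(out, "range_events.csv"), row.names = FALSE)
cat(sprintf("ranges: %d tips, %d placed events (root %s)\n",
            length(h$ranges), nrow(h$events),
            paste(h$root_range, collapse = "+")))

d <- gen_allometry(n = 12, slope = 1.05, intercept = 100, sigma = 10,
                   x_range = c(250, 450), seed = seed + 3)
write.csv(d$data, file.path(out, "allometry.csv"), row.names = FALSE)
cat(sprintf("allometry: n = %d, true slope %.2f, sigma %.0f mm\n",
            nrow(d$data), d$truth$slope, d$truth$sigma))
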