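#!/usr/bin/env Rscript

# Group-contrast survey over locally downloaded rhodopsin/opsin PDB files.
#
# Usage: Rscript scripts/rhodopsin_contrasts.R <dir-with-pdb-files> [out.tsv]
#
# Expects a directory of PDB/mmCIF files named by their PDB codes (e.g.
# 1U19.pdb, 3CAP.pdb). Uses the shipped segment and group configs
# (inst/extdata/rhodopsin_segments.yaml / rhodopsin_groups.yaml) — edit the
# group membership there to match the entries you have. No network access
# is attempted: fetch the files yourself, e.g. from https://files.rcsb.org.
#
# Reported contrasts (group 1 = ground state + early intermediates,
# group 3 = opsin/meta-II):
#   TM5c unwinding            omega(TM5c): group3 - group1
#   TM5 differential winding  omega(TM5e) - omega(TM5c), group 3
#   TM1 differential winding  omega(TM1e) - omega(TM1c), all structures
#   TM5m pi diameter excess   diameter(TM5m) - mean diameter(TM5e, TM5c)
#   TM5m pi winding deficit   omega(TM5m) - mean omega(TM5e, TM5c)
#   TM7m anchor winding shift omega(TM7m): group3 - group1
#   TM7 e/c diameter contrast diameter(TM7e) - diameter(TM7c), group 1

suppressPackageStartupMessages(library(helixforge))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1)
  stop("usage: Rscript scripts/rhodopsin_contrasts.R <pdb dir> [out.tsv]")
dir <- args[1]
out <- if (length(args) >= 2) args[2] else "rhodopsin_contrasts.tsv"
files <- list.files(dir, pattern = "\\.(pdb|ent|cif|mmcif)$", full.names = TRUE)
if (length(files) == 0) stop("no structure files in '", dir, "'")

segCfg <- system.file("extdata", "rhodopsin_segments.yaml", package = "helixforge")
grpCfg <- system.file("extdata", "rhodopsin_groups.yaml", package = "helixforge")

tbl <- cmdFit(files, segCfg, groupConfig = grpCfg)
tbl <- tbl[tbl$converged, , drop = FALSE]

halfMean <- function(t, seg1, seg2, col, grp = NULL) {
  keep <- if (is.null(grp)) rep(TRUE, nrow(t)) else t$group_id %in% grp
  (t[[col]][keep & t$segment == seg1] + t[[col]][keep & t$segment == seg2]) / 2
}

contrasts <- data.frame(
  contrast = c("TM5c_unwinding_deg_per_res",
               "TM5_differential_winding_group3",
               "TM1_differential_winding",
               "TM5m_pi_diameter_excess_A",
               "TM5m_pi_winding_deficit_deg_per_res",
               "TM7m_anchor_winding_shift_deg_per_res",
               "TM7_ec_diameter_contrast_group1_A"),
  value = c(
    groupContrast(tbl, "TM5c", "omega", 3, 1),
    segmentContrast(tbl, "TM5e", "TM5c", "omega", group = 3),
    segmentContrast(tbl, "TM1e", "TM1c", "omega"),
    mean(tbl$diameter[tbl$segment == "TM5m"]) -
      mean(halfMean(tbl, "TM5e", "TM5c", "diameter")),
    mean(tbl$omega[tbl$segment == "TM5m"]) -
      mean(halfMean(tbl, "TM5e", "TM5c", "omega")),
    groupContrast(tbl, "TM7m", "omega", 3, 1),
    segmentContrast(tbl, "TM7e", "TM7c", "diameter", group = 1)))

write.table(contrasts, out, sep = "\t", quote = FALSE, row.names = FALSE)
print(contrasts, row.names = FALSE)
cat("full parameter table rows:", nrow(tbl), "\n")
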