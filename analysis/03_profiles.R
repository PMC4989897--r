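#!/usr/bin/env Rscript
# Step 3: mark metaprofiles around region centers.
#
# Binned mean DHS and H3K27ac coverage in +/- 5 kb windows (200 x 50 bp
# bins) around eCGIs, typical enhancers and pCGIs — the enhancer-signature
# comparison across the three region classes.

suppressMessages(library(ecgi))

ds <- read_dataset("results/synthetic")
cl <- classify_cgis(ds$cgis, ds$genes, ds$h3k27ac_peaks, ds$dhs_peaks,
                    ds$cage_tss, ds$denovo_tss)
te <- call_typical_enhancers(ds$h3k27ac_peaks, ds$dhs_peaks, ds$cage_tss,
                             ds$denovo_tss, ds$cgis)
region_sets <- list(eCGI = cl[cl$label == "eCGI", ],
                    typical_enhancer = te,
                    pCGI = cl[cl$label == "pCGI", ])
tracks <- list(dhs = ds$coverage$dhs_normal,
               h3k27ac = ds$coverage$h3k27ac_normal)

dir.create("results/profiles", recursive = TRUE, showWarnings = FALSE)
for (rs in names(region_sets)) {
  for (tr in names(tracks)) {
    prof <- metaprofile(region_sets[[rs]], tracks[[tr]],
                        flank = 5000, n_bins = 200)
    write_metaprofile(prof,
                      sprintf("results/profiles/%s_%s.tsv", rs, tr))
    cat(sprintf("%-17s x %-8s peak bin signal %.2f (center +/- 500 bp mean %.2f)\n",
                rs, tr, max(prof$bin_values),
                mean(prof$bin_values[abs(prof$offsets) < 500])))
  }
}
cat("Profiles written under results/profiles/\n")
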