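#!/usr/bin/env Rscript

# Stage 4 — sequence-logo matrices (residue frequencies + information
# content) per assigned group; the numerical content of the family's CSR
# logos.

suppressMessages(library(gh57csr))

cfg <- synthetic_config()
det <- gh57csr:::read_tsv_with_header("results/fingerprints.tsv")
asg <- gh57csr:::read_tsv_with_header("results/assignments.tsv")

ok <- asg$label != "eliminated"
fps <- split(det$fingerprint[ok], asg$label[ok])
logos <- lapply(names(fps), function(g)
  logo_from_fingerprints(fps[[g]], group = g))
names(logos) <- names(fps)
write_logos_json(logos, "results/logos.json", meta = list(seed = cfg$seed))

for (g in intersect(c("AAMY", "GBE", "AGAL"), names(logos)))
  write_logo_tsv(logos[[g]], sprintf("results/logo_%s.tsv", g))

for (g in names(logos)) {
  lg <- logos[[g]]
  cons <- logo_consensus(lg)
  message(sprintf(
    "%-14s n=%4d  IC15=%.2f IC20=%.2f bits  pos23=%s  pair35-36=%s%s",
    g, lg$n, lg$ic[15], lg$ic[20], cons[23], cons[35], cons[36]))
}
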