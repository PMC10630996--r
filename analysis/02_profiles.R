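#!/usr/bin/env Rscript
# Meta-exon profiles: normalized eCLIP 5'-end and ipaRt read-midpoint
# distributions relative to the exon junction, with their peak positions.
source("analysis/00_config.R")

exp <- load_experiment()

prof5 <- fiveprime_profile(rbindlist(exp$reads$eclip), exp$exons)
profm <- midpoint_profile(rbindlist(exp$reads$ipart), exp$exons)
prof_bg <- fiveprime_profile(rbindlist(exp$reads$sminput), exp$exons)

write_profile(prof5, file.path(results_dir, "profile_eclip_fiveprime.tsv"))
write_profile(profm, file.path(results_dir, "profile_ipart_midpoint.tsv"))
write_profile(prof_bg, file.path(results_dir, "profile_sminput_fiveprime.tsv"))

cat(sprintf("eCLIP 5'-end peak:    %d nt upstream of the junction\n",
            -peak_position(prof5)))
cat(sprintf("ipaRt midpoint peak:  %d nt upstream of the junction\n",
            -peak_position(profm)))
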