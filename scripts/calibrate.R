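#!/usr/bin/env Rscript
# Calibration helper: simulates each segment kind at its default amplitude
# tier and prints per-epoch band powers and detector outcomes, so the
# default thresholds and intensity anchors in pd_config() can be set (and
# audited) against the generator's signal models.
suppressMessages(library(wristpd))
cfg <- pd_config()
kinds <- segment_kinds
cat(sprintf("%-18s %9s %9s %9s %9s %9s %9s %6s %6s %6s %6s\n",
            "kind", "p37", "p053", "p13", "p38", "p18", "p_act",
            "trem%", "brady%", "dyskf%", "act%"))
for (k in kinds) {
  sc <- simulation_script(data.frame(kind = k, duration_s = 1800),
                          seed = 42)
  sim <- simulate_recording(sc)
  ef <- wristpd:::epoch_features(sim$recording, cfg)$feat
  cat(sprintf("%-18s %9.2e %9.2e %9.2e %9.2e %9.2e %9.2e %5.1f%% %5.1f%% %5.1f%% %5.1f%%\n",
              k, median(ef$p37), median(ef$p053), median(ef$p13),
              median(ef$p38), median(ef$p18), median(ef$p_act),
              100*mean(ef$tremor), 100*mean(ef$brady),
              100*mean(ef$dysk_flag), 100*mean(ef$active)))
  if (k %in% c("dyskinesia_mild", "dyskinesia_severe"))
    cat(sprintf("   max gated dysk intensity: %.2f\n",
                max(ef$dysk_intensity)))
}
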