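#!/usr/bin/env Rscript
# Step 4: figures.
#
# Group-mean waveforms over the normalized gait cycle: knee flexion angle,
# knee frontal net moment, contact-force components, and the summed
# extensor/flexor activations with the pointwise EFAR trace.

suppressMessages({
  library(oagait)
  library(ggplot2)
})

sub_dir <- file.path("results", "analysis", "subjects")
fig_dir <- file.path("results", "analysis", "figures")
dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)
waves <- read.csv(file.path(sub_dir, "subject_waveforms.csv"), comment.char = "#")

group_mean <- aggregate(
  waves[, c("A_e", "A_f", "efar_series", "compressive_bw", "ml_bw", "ap_bw",
            "knee_flexion_deg", "knee_frontal_moment_bw")],
  by = list(group = waves$group, cycle_pct = waves$cycle_pct),
  FUN = mean, na.rm = TRUE)

theme_set(theme_bw(base_size = 11))

p1 <- ggplot(group_mean, aes(cycle_pct, knee_flexion_deg, colour = group)) +
  geom_line(linewidth = 0.8) +
  labs(x = "Gait cycle (%)", y = "Knee flexion (deg)",
       title = "Group-mean knee flexion")
ggsave(file.path(fig_dir, "knee_flexion.png"), p1, width = 6, height = 4, dpi = 150)

p2 <- ggplot(group_mean, aes(cycle_pct, compressive_bw, colour = group)) +
  geom_line(linewidth = 0.8) +
  labs(x = "Gait cycle (%)", y = "Axial contact force (BW, negative = compressive)",
       title = "Knee axial contact force")
ggsave(file.path(fig_dir, "contact_compressive.png"), p2, width = 6, height = 4, dpi = 150)

p3 <- ggplot(group_mean, aes(cycle_pct, ml_bw, colour = group)) +
  geom_line(linewidth = 0.8) +
  labs(x = "Gait cycle (%)", y = "ML contact force (BW, positive = medial)",
       title = "Knee mediolateral contact force")
ggsave(file.path(fig_dir, "contact_ml.png"), p3, width = 6, height = 4, dpi = 150)

act <- reshape(group_mean[, c("group", "cycle_pct", "A_e", "A_f")],
               direction = "long", varying = c("A_e", "A_f"),
               v.names = "activation", timevar = "muscle_group",
               times = c("extensors", "flexors"))
p4 <- ggplot(act, aes(cycle_pct, activation, colour = group,
                      linetype = muscle_group)) +
  geom_line(linewidth = 0.8) +
  labs(x = "Gait cycle (%)", y = "Summed group activation",
       title = "Knee extensor and flexor activation sums")
ggsave(file.path(fig_dir, "group_activations.png"), p4, width = 6, height = 4, dpi = 150)

p5 <- ggplot(group_mean, aes(cycle_pct, efar_series, colour = group)) +
  geom_line(linewidth = 0.8) +
  labs(x = "Gait cycle (%)", y = "EFAR (pointwise)",
       title = "Extensor/flexor activation ratio over the cycle")
ggsave(file.path(fig_dir, "efar_series.png"), p5, width = 6, height = 4, dpi = 150)

message("Wrote 5 figures to ", fig_dir)
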