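#!/usr/bin/env Rscript
# Bifurcation structure of the calibrated CBSD model: TGF0 diagrams in
# control and knockdown, the ks1 diagram at the knockdown ML point, the
# k_knockdown diagram at 10 ng/ml, window edges, and the
# k_knockdown x TGF0 phenotype state matrix.
#
# Outputs (results/): diagram_{tgf0_control,tgf0_knockdown,ks1,kkd}.csv
#   (+ *_folds.csv), window_edges.json, state_matrix.csv,
#   manifest_04.json

library(cbsd)
dir.create("results", showWarnings = FALSE)
p <- cbsd_params()
th <- phenotype_thresholds(p)

edges <- list()

dg_ctl <- assemble_diagram(p, cbsd_condition(0), "TGF0", c(0, 10))
print(dg_ctl)
write_diagram_csv(dg_ctl, "results/diagram_tgf0_control.csv")

dg_kd <- assemble_diagram(p, cbsd_condition(0, TRUE, ml_knockdown_fraction()), "TGF0",
                          c(0, 10))
print(dg_kd)
write_diagram_csv(dg_kd, "results/diagram_tgf0_knockdown.csv")
# largest dose with a stable low-N-cad (E) branch under knockdown
e_pts <- do.call(rbind, lapply(dg_kd$branches, function(b) b$points))
eE <- e_pts[e_pts$stable & e_pts$Ncad < th[1], ]
edges$E_branch_max_dose <- max(eE$param)
message(sprintf("knockdown E branch stable up to TGF0 = %.2f ng/ml",
                edges$E_branch_max_dose))

dg_ks1 <- assemble_diagram(p, cbsd_condition(10, TRUE, ml_knockdown_fraction()), "ks1",
                           c(1e-4, 0.03))
print(dg_ks1)
write_diagram_csv(dg_ks1, "results/diagram_ks1.csv")
message(sprintf("ks1 diagram: %d saddle-node bifurcations", dg_ks1$n_folds))
pts <- do.call(rbind, lapply(dg_ks1$branches, function(b) b$points))
stE <- pts[pts$stable & pts$Ncad < th[1], ]
stP <- pts[pts$stable & pts$Ncad >= th[1] & pts$Ncad < th[2], ]
stM <- pts[pts$stable & pts$Ncad >= th[2], ]
edges$ks1_E_branch_end <- max(stE$param)
edges$ks1_PM_coexist_upper <- max(stP$param[stP$param >= min(stM$param)])
edges$ks1_n_folds <- dg_ks1$n_folds
message(sprintf(
  "ks1 windows: E ends %.4f; P/M coexist up to %.4f µM/h",
  edges$ks1_E_branch_end, edges$ks1_PM_coexist_upper))

dg_kkd <- assemble_diagram(p, cbsd_condition(10, TRUE, 0.5),
                           "k_knockdown", c(0, 1))
print(dg_kkd)
write_diagram_csv(dg_kkd, "results/diagram_kkd.csv")
kpts <- do.call(rbind, lapply(dg_kkd$branches, function(b) b$points))
kE <- kpts[kpts$stable & kpts$Ncad < th[1], ]
kP <- kpts[kpts$stable & kpts$Ncad >= th[1] & kpts$Ncad < th[2], ]
# window where the stable partial branch coexists with the E branch
lo <- max(min(kP$param), min(kE$param))
hi <- min(max(kP$param), max(kE$param))
edges$kkd_window_lower_pct <- 100 * lo
edges$kkd_window_upper_pct <- 100 * hi
message(sprintf(
  "k_knockdown E/P coexistence window: %.1f%% to %.1f%%",
  edges$kkd_window_lower_pct, edges$kkd_window_upper_pct))

jsonlite::write_json(edges, "results/window_edges.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

sm <- state_matrix(p,
                   list(name = "k_knockdown",
                        values = seq(0, 1, by = 0.1)),
                   list(name = "TGF0", values = seq(0, 10, by = 1)),
                   t_end = 5 * time_units_per_day())
write.csv(sm, "results/state_matrix.csv", quote = FALSE)
message("state matrix (rows k_knockdown, cols TGF0):")
print(sm)
write_manifest("results/manifest_04.json",
               config = list(ks1_range = c(1e-4, 0.03)))
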