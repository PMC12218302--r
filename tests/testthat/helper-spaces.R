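# fixture design spaces mirroring the two case-study geometries

co_feed_types <- c("Ethanol", "Glycerol", "Sorbitol", "Xylitol", "Mannitol",
                   "Glucose", "Fructose", "Galactose", "Mannose", "Trehalose",
                   "Lactose", "Ribose", "Sucrose", "Rhamnose", "D-Arabinose",
                   "Xylose", "Citrate", "Pyruvate", "Succinate")

yeast_space <- function() {
  design_space(
    design_factor("Glycerol", "continuous", 0, 10, units = "%",
                  phase = "Outgrowth"),
    design_factor("Methanol", "continuous", 0, 10, units = "%",
                  phase = "Production"),
    design_factor("CoFeedType", "categorical", categories = co_feed_types,
                  phase = "Production"),
    design_factor("CoFeedConc", "continuous", 0, 50, units = "g/L",
                  phase = "Production", linked_to = "CoFeedType"))
}

blend_space <- function(k = 4) {
  nms <- c("DMEM", "AR5", "XVIVO", "RPMI")[seq_len(k)]
  design_space(lapply(nms, function(nm) {
    design_factor(nm, "continuous", 0, 1)
  }), constraints = list(constraint_sum_to_one(nms)))
}

toy1d_space <- function() {
  design_space(design_factor("x", "continuous", 0, 1))
}

small_mixed_space <- function(n_cats = 3) {
  design_space(
    design_factor("x1", "continuous", 0, 1),
    design_factor("x2", "continuous", 0, 1),
    design_factor("cat", "categorical",
                  categories = paste0("c", seq_len(n_cats))))
}

# deterministic smooth test function on the small mixed space
mixed_test_fun <- function(df) {
  off <- c(c1 = 0, c2 = 0.5, c3 = -0.3, c4 = 0.2)
  sin(2 * pi * df$x1) * 0.5 + (df$x2 - 0.3)^2 + off[as.character(df$cat)]
}
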