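#!/usr/bin/env Rscript
# Step 2 — base-case costing.
#
# Reads the simulated survey and the unit-cost configuration, computes
# per-caregiver direct and indirect costs, and aggregates them with the
# survey weights into national cost tables for every valuation cell:
# {opportunity cost, proxy good} x {human capital, friction cost}.
# Writes one table per method plus macro context metrics.

suppressPackageStartupMessages(library(carecost))

records <- read_microdata("results/microdata_synthetic.csv")
costs <- load_unit_costs(system.file("extdata", "unit_costs_synthetic.yaml",
                                     package = "carecost"))

work_stats <- compute_rhw_delta(records)
cat(sprintf(paste0("weekly work hours: non-caregivers %.2f, reducers ",
                   "%.2f -> reduced-hours delta %.2f h/week\n"),
            work_stats$mean_workhours_noncaregivers,
            work_stats$mean_workhours_reducers, work_stats$rhw_delta))

breakdown <- cost_breakdown(records, costs, work_stats = work_stats)
report <- aggregate_costs(breakdown)
print(report)

dir.create("results", showWarnings = FALSE)
flat <- do.call(rbind, lapply(names(report$cells), function(cell) {
  cbind(cell = cell, report$cells[[cell]])
}))
write.csv(flat[startsWith(flat$cell, "oc"), ],
          "results/table_costs_opportunity_cost.csv", row.names = FALSE)
write.csv(flat[startsWith(flat$cell, "pg"), ],
          "results/table_costs_proxy_good.csv", row.names = FALSE)

ctx <- context_metrics(report$totals[["oc_fca"]], breakdown, costs)
ctx_hi <- context_metrics(report$totals[["pg_hca"]], breakdown, costs)
cat(sprintf("\ntotal informal care: %.2f billion hours = %.0f FTE years\n",
            ctx$total_care_hours / 1e9, ctx$fte_equivalents))
cat(sprintf("total societal cost: %.1f-%.1f billion EUR (%.2f%%-%.2f%% of GDP)\n",
            report$totals[["oc_fca"]] / 1e9, report$totals[["pg_hca"]] / 1e9,
            ctx$pct_of_gdp, ctx_hi$pct_of_gdp))
cat(sprintf("per-adult contribution: %.0f-%.0f EUR/year\n",
            ctx$per_adult_contribution, ctx_hi$per_adult_contribution))
jsonlite::write_json(list(low = ctx, high = ctx_hi),
                     "results/context_metrics.json",
                     auto_unbox = TRUE, digits = NA)
cat("\nwrote results/table_costs_*.csv and results/context_metrics.json\n")
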