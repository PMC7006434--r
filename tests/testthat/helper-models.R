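# Small fixture models built in code.

# linear chain: E_in (uptake <= cap) -> A -> E_out
chain_model <- function(cap = 5) {
  mets <- rbind(metabolite("a[e]", formula = "C1"),
                metabolite("a[c]", formula = "C1"))
  rxns <- list(
    reaction("E_in", c("a[e]" = -1), reversible = TRUE, lb = -cap, ub = 0),
    reaction("At", c("a[e]" = -1, "a[c]" = 1), reversible = TRUE),
    reaction("E_out", c("a[c]" = -1), lb = 0, ub = 1000))
  metabolic_model(mets, rxns, objective_id = "E_out")
}

# two equivalent parallel routes from a[c] to b[c]
parallel_model <- function(cap = 4) {
  mets <- rbind(metabolite("a[e]"), metabolite("a[c]"), metabolite("b[c]"))
  rxns <- list(
    reaction("E_in", c("a[e]" = -1), reversible = TRUE, lb = -cap, ub = 0),
    reaction("At", c("a[e]" = -1, "a[c]" = 1), reversible = TRUE),
    reaction("P1", c("a[c]" = -1, "b[c]" = 1)),
    reaction("P2", c("a[c]" = -1, "b[c]" = 1)),
    reaction("E_out", c("b[c]" = -1)))
  metabolic_model(mets, rxns, objective_id = "E_out")
}

# chain with an internal 2-cycle (x <-> y both directions) that can carry
# arbitrary circulating flux without affecting the objective
cycle_model <- function(cap = 3) {
  mets <- rbind(metabolite("x[c]"), metabolite("y[c]"))
  rxns <- list(
    reaction("E_in", c("x[c]" = -1), reversible = TRUE, lb = -cap, ub = 0),
    reaction("F1", c("x[c]" = -1, "y[c]" = 1)),
    reaction("F2", c("y[c]" = -1, "x[c]" = 1)),
    reaction("E_out", c("y[c]" = -1)))
  metabolic_model(mets, rxns, objective_id = "E_out")
}

# two-stage toy where knocking out a reaction lowers the stage-1 optimum and
# raises the stage-2 value: objectives O1 and O2 compete for a shared
# precursor s[c] (supply <= 2); O1 additionally needs p[c] via reaction RP.
lexi_model <- function() {
  mets <- rbind(metabolite("s[c]"), metabolite("p[c]"),
                metabolite("w1[c]"), metabolite("w2[c]"))
  rxns <- list(
    reaction("E_s", c("s[c]" = -1), reversible = TRUE, lb = -2, ub = 0),
    reaction("E_p", c("p[c]" = -1), reversible = TRUE, lb = -10, ub = 0),
    reaction("RP", c("p[c]" = -1, "w1[c]" = 1)),
    reaction("O1", c("s[c]" = -1, "w1[c]" = -1)),
    reaction("O2", c("s[c]" = -1, "w2[c]" = 1)),
    reaction("E_w2", c("w2[c]" = -1)))
  metabolic_model(mets, rxns, objective_id = "O1")
}

# randomized small network with deliberately blocked parts; seeded
random_blocked_model <- function(seed) {
  set.seed(seed)
  mets <- rbind(metabolite("a[e]"), metabolite("a[c]"), metabolite("b[c]"),
                metabolite("c[c]"), metabolite("c[e]"), metabolite("d[c]"),
                metabolite("f[c]"), metabolite("g[c]"))
  rxns <- list(
    reaction("EX_a", c("a[e]" = -1), reversible = TRUE),
    reaction("At", c("a[e]" = -1, "a[c]" = 1), reversible = TRUE),
    reaction("R1", c("a[c]" = -1, "b[c]" = 1),
             reversible = stats::runif(1) < 0.5),
    reaction("R2", c("b[c]" = -1, "c[c]" = 1)),
    reaction("Ct", c("c[c]" = -1, "c[e]" = 1), reversible = TRUE),
    reaction("EX_c", c("c[e]" = -1), reversible = TRUE),
    # dead-end branch: d has no other producer/consumer
    reaction("DEAD", c("d[c]" = -1, "b[c]" = 1)),
    # isolated pair f -> g with no boundary access
    reaction("ISO1", c("f[c]" = -1, "g[c]" = 1),
             reversible = stats::runif(1) < 0.5),
    reaction("ISO2", c("g[c]" = -1, "f[c]" = 1)),
    # maybe-blocked side branch: b -> f opens ISO1/ISO2 only if g sink exists
    reaction("SIDE", c("b[c]" = -1, "f[c]" = 1)),
    if (stats::runif(1) < 0.5)
      reaction("EX_g", c("g[c]" = -1), reversible = TRUE)
    else
      reaction("R3", c("c[c]" = -1, "b[c]" = 1)),
    reaction("R4", c("a[c]" = -1, "c[c]" = 1,
                     "b[c]" = if (stats::runif(1) < 0.5) 1 else -1)))
  metabolic_model(mets, rxns, objective_id = "EX_c")
}

toy_table1_path <- function()
  system.file("extdata", "table1_objectives.tsv", package = "gliaflux",
              mustWork = TRUE)
toy_table2_path <- function()
  system.file("extdata", "table2_tibolone.tsv", package = "gliaflux",
              mustWork = TRUE)
toy_medium_path <- function()
  system.file("extdata", "dmem_medium.tsv", package = "gliaflux",
              mustWork = TRUE)
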