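#' Synthetic 22-item case network (illustrative stand-in)
#'
#' A hand-constructed, **synthetic** regularized lag-1 network over the 22
#' daily mood-and-anxiety items of the package's motivating case study
#' (five Depression, five Anxiety, three Mixed, five Anhedonia, four
#' Positive Affect items). The participant's estimated matrix is not
#' publicly deposited, so this object encodes only the published summary
#' structure: exactly 51 of the 484 possible lag-1 relations are nonzero;
#' the three dynamically isolated items ("Noth Fun", "Up", "Happy") have no
#' relations at all; "Trb Conc" (trouble concentrating) is the hub, with
#' positive lagged inputs from "Uneasy", "Discourage" and itself and
#' negative inputs from "Sad", "Depressed", "Not Enjoy", "Blame" and
#' "Extra Effort", and outputs to "Not Enjoy", "Extra Effort", "Slow",
#' "Withdraw" and (negatively) "Energy"; "Discourage" carries the
#' strongest autoregressive self-loop; "Tense" has the largest total
#' out-strength; and the "Nervous"/"On Edge" pair forms a mutual positive
#' feedback loop. Edge magnitudes are plausible round values on the
#' standardized scale and are **not** the case study's estimates — use
#' this object to exercise the pruning, centrality, community and
#' reporting stages, not to reproduce published coefficients.
#'
#' @return A [lag_network()] with 22 nodes.
#' @export
synthetic_case_network <- function() {
  items <- c("Sad", "Depressed", "Discourage", "Disappoint", "Blame",
             "Nervous", "Tense", "Uneasy", "Un Relax", "On Edge",
             "Worry", "Trb Conc", "Confused",
             "Not Enjoy", "Withdraw", "Noth Fun", "Extra Effort", "Slow",
             "Up", "Happy", "Fun", "Energy")
  edges <- rbind(
    # origin, destination, weight
    c("Discourage",   "Discourage",    0.45),  # strong persistence
    c("Trb Conc",     "Trb Conc",      0.30),
    c("Worry",        "Worry",         0.30),
    c("Sad",          "Sad",           0.15),
    c("Uneasy",       "Uneasy",        0.15),
    # lagged inputs to Trb Conc
    c("Uneasy",       "Trb Conc",      0.30),
    c("Discourage",   "Trb Conc",      0.40),
    c("Sad",          "Trb Conc",     -0.15),
    c("Depressed",    "Trb Conc",     -0.15),
    c("Not Enjoy",    "Trb Conc",     -0.20),
    c("Blame",        "Trb Conc",     -0.10),
    c("Extra Effort", "Trb Conc",     -0.25),
    # lagged outputs of Trb Conc
    c("Trb Conc",     "Not Enjoy",     0.30),
    c("Trb Conc",     "Extra Effort",  0.35),
    c("Trb Conc",     "Slow",          0.25),
    c("Trb Conc",     "Energy",       -0.20),
    c("Trb Conc",     "Withdraw",      0.20),
    # discouragement hub
    c("Discourage",   "Worry",         0.40),
    c("Slow",         "Discourage",    0.20),
    c("Not Enjoy",    "Discourage",    0.25),
    c("Sad",          "Discourage",    0.20),
    # anxiety cluster: tension drives, nervous/on-edge reciprocate
    c("Nervous",      "On Edge",       0.25),
    c("On Edge",      "Nervous",       0.20),
    c("Tense",        "Uneasy",        0.35),
    c("Tense",        "On Edge",       0.35),
    c("Tense",        "Un Relax",      0.35),
    c("Tense",        "Nervous",       0.30),
    c("Tense",        "Worry",         0.25),
    c("Tense",        "Sad",           0.25),
    c("Un Relax",     "Tense",         0.15),
    c("Nervous",      "Uneasy",        0.20),
    c("Uneasy",       "On Edge",       0.15),
    c("Confused",     "Uneasy",        0.15),
    # worry radiates
    c("Worry",        "Uneasy",        0.25),
    c("Worry",        "Sad",           0.20),
    c("Worry",        "Nervous",       0.20),
    c("Worry",        "Confused",      0.20),
    c("Worry",        "On Edge",       0.15),
    c("Worry",        "Un Relax",      0.20),
    # anhedonia / withdrawal periphery
    c("Withdraw",     "Not Enjoy",     0.20),
    c("Slow",         "Not Enjoy",     0.15),
    c("Withdraw",     "Sad",           0.20),
    c("Slow",         "Extra Effort",  0.15),
    c("Depressed",    "Slow",          0.25),
    c("Depressed",    "Withdraw",      0.20),
    c("Disappoint",   "Blame",         0.25),
    c("Blame",        "Disappoint",    0.20),
    c("Energy",       "Fun",           0.25),
    c("Fun",          "Energy",        0.20),
    c("Slow",         "Energy",       -0.20),
    c("Withdraw",     "Fun",          -0.15))
  W <- matrix(0, length(items), length(items),
              dimnames = list(items, items))
  W[cbind(match(edges[, 1], items), match(edges[, 2], items))] <-
    as.numeric(edges[, 3])
  lag_network(W, items, provenance = list(source = "synthetic stand-in"))
}
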