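# Independent oracles and frozen expected values.
#
# The frozen constants below were computed with an independent numerical
# oracle (numpy): de-decay-correct the printed tumor %ID/g rows with
# T1/2 = 64.1 h, hand-trapezoid with a (0, 0) anchor over days 0-10.

# trapezoid by the summation formula, independent of the package's
# integration path
oracle_trapz <- function(t, y) {
  sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
}

ORACLE <- list(
  lambda_64p1 = 0.0108135,           # ln(2)/64.1, calculator
  df_24h = 0.7714182,                # exp(-ln2 * 24/64.1)
  auc1_pidg_day = 44.18422383558653, # 12A8 tumor, zero-anchored trapezoid
  auc2_pidg_day = 71.98886923046427, # 67A2 tumor
  dose1_3p7_Gy = 21.116512433106,    # 3.7 MBq x AUC1 x 864000 x 1.495e-13
  dose2_3p7_Gy = 34.404901120521     # same for the 67A2 table
)

study_days <- c(1, 2, 4, 7, 10)
tumor_row_12A8 <- c(7.3, 16.7, 18.9, 11.1, 13.4)
tumor_row_67A2 <- c(15.7, 23.8, 31.5, 18.2, 16.7)

y90 <- get_nuclide("90Y")
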