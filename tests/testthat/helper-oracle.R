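# brute-force savings oracle: plain loops over individual records, written
# independently of the package's dplyr pipeline

oracle_round <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# matched (form, strength) keys of a molecule: those its biosimilar sells
oracle_matched_keys <- function(df, molecule, bio_brand) {
  sel <- df$molecule == molecule & df$brand == bio_brand &
    df$role == "biosimilar"
  unique(paste(df$form[sel], df$strength[sel], sep = "|"))
}

# per-molecule realized/unrealized at one stratification
oracle_savings <- function(df, pairing = default_pairing(),
                           level = c("national", "region"),
                           convention = c("cent_rounded", "exact")) {
  level <- match.arg(level)
  convention <- match.arg(convention)
  df <- as.data.frame(df)
  out <- data.frame()
  for (i in seq_len(nrow(pairing))) {
    mol <- pairing$molecule[i]
    ob <- pairing$originator_brand[i]
    bb <- pairing$biosimilar_brand[i]
    keys <- oracle_matched_keys(df, mol, bb)
    in_scope <- df$molecule == mol &
      paste(df$form, df$strength, sep = "|") %in% keys
    if (!any(in_scope)) next
    strata <- if (level == "region") unique(df$region[in_scope]) else "ALL"

    # national fallback delta for regions without biosimilar sales
    od_all <- sum(df$dollars[in_scope & df$brand == ob])
    ou_all <- sum(df$units[in_scope & df$brand == ob])
    bd_all <- sum(df$dollars[in_scope & df$brand == bb])
    bu_all <- sum(df$units[in_scope & df$brand == bb])
    nat_delta <- oracle_delta(od_all / ou_all, bd_all / bu_all, convention)

    for (s in strata) {
      sel <- in_scope & (if (level == "region") df$region == s else TRUE)
      ou <- sum(df$units[sel & df$brand == ob])
      bu <- sum(df$units[sel & df$brand == bb])
      delta <- if (bu > 0 && ou > 0) {
        oracle_delta(sum(df$dollars[sel & df$brand == ob]) / ou,
                     sum(df$dollars[sel & df$brand == bb]) / bu, convention)
      } else {
        nat_delta
      }
      out <- rbind(out, data.frame(
        molecule = mol, stratum = s,
        realized = oracle_round(delta * bu),
        unrealized = if (ou == 0) 0 else oracle_round(delta * ou)))
    }
  }
  out
}

oracle_delta <- function(op, bp, convention) {
  if (convention == "cent_rounded") {
    oracle_round(oracle_round(op, 2) - oracle_round(bp, 2), 2)
  } else {
    op - bp
  }
}
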