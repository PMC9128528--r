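# fast aligned merge of a generated exposure/outcome pair into the
# harmonized-instrument layout (the generator reports both studies on the
# same strand and effect allele, so this is the identity alignment; the
# harmonization logic itself is exercised in its own tests)
merge_ivs <- function(d) {
  data.frame(
    snp = d$exposure$snp, ea = d$exposure$ea, oa = d$exposure$oa,
    eaf_exp = d$exposure$eaf, beta_exp = d$exposure$beta,
    se_exp = d$exposure$se, p_exp = d$exposure$p,
    eaf_out = d$outcome$eaf, beta_out = d$outcome$beta,
    se_out = d$outcome$se, p_out = d$outcome$p,
    n_exp = d$exposure$n, n_out = d$outcome$n,
    flags = "", stringsAsFactors = FALSE
  )
}
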