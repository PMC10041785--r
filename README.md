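# aedisparity

Host-factor disparity tests for spontaneous adverse-event reporting
databases.

Drug toxicity does not strike all patients equally: sex, age and other host
factors can modify the risk of a specific adverse event (AE) for a specific
drug. Spontaneous reporting systems such as FAERS hold millions of reports
and are the only human data source large enough to screen for such
drug–host interactions — but the question is different from classical
safety-signal detection, and it needs tests with proper type-I error
control. `aedisparity` is for pharmacoepidemiologists and biostatisticians
who want to screen a family of drugs (for one AE) or a family of AEs (for
one drug) for unusual disparities between two host-factor groups, with
family-wise error or false-discovery-rate control.

## The model and the tests

For AE *i* and drug *j*, reports are tabulated in a 2×2 table by drug
exposure and host-factor group, with exposed cells
(n⁽¹⁾ᵢⱼ, n⁽²⁾ᵢⱼ), exposed total n = n⁽¹⁾ᵢⱼ + n⁽²⁾ᵢⱼ, group margins
M₁ = n⁽¹⁾ᵢ·, M₂ = n⁽²⁾ᵢ·, and N = M₁ + M₂. Conditioning Poisson cell counts
on the margins gives the null

    n⁽¹⁾ᵢⱼ | n, M₁, M₂  ~  Binomial(n, p),   p = M₁/N,

i.e. under no drug–host interaction a drug's exposed reports split between
the groups like the whole family does. Four tests of this null are
provided, applied to every table of the family:

| test | statistic | null distribution |
|---|---|---|
| `lrt` | LR = −n log(n/N) + n⁽¹⁾ log(n⁽¹⁾/M₁) + n⁽²⁾ log(n⁽²⁾/M₂) | Monte-Carlo (binomial resampling) |
| `normal` | z = √n (n⁽¹⁾/n − p)/√(p(1−p)) | N(0, 1) |
| `prr` | delta-method z for log PRR | N(0, 1) |
| `ror` | delta-method z for log ROR | N(0, 1) |

Multiplicity over the J tables of a family is handled by the Max-Stat
step-down procedure (reject where the statistic exceeds the (1−α) quantile
of the family maximum under the global null — Monte-Carlo for the LRT,
Φ⁻¹((1−α/2)^(1/J)) for the z-based tests) or by Benjamini–Hochberg. A
simulation harness with a synthetic-base generator estimates empirical
FWER, FDR and sensitivity for all method × adjustment combinations.

## Worked example

The package ships the 12-analgesic liver-toxicity family (sex as host
factor; group margins male 47830 / female 53078) as a plain-TSV fixture:

```r
library(aedisparity)
fam <- read_table_family(
  system.file("extdata", "analgesics_sex_family.tsv", package = "aedisparity"),
  group_labels = c("male", "female"))
fit <- disparity_test(fam, methods = c("lrt", "normal"),
                      adjust = "maxstat", m = 1e5, seed = 1)
print(fit)
```

```
Host-factor disparity tests (by_drug), context 'liver toxicity'
12 tables; groups male/female; adjustment: Max-Stat at alpha = 0.05
       unit_id method statistic estimate  p_raw p_adjusted rejected
 acetaminophen    lrt   67.2388       NA <1e-05     <1e-05     TRUE
       aspirin    lrt    6.1345       NA 0.0006     0.0071     TRUE
     ibuprofen    lrt    4.4538       NA 0.0028     0.0424     TRUE
     meloxicam    lrt    4.3995       NA 0.0048     0.0453     TRUE
      etodolac    lrt    3.1308       NA 0.0159     0.1471    FALSE
           ...
 acetaminophen normal  -11.5059       NA 0.0000     0.0000     TRUE
       aspirin normal    3.5011       NA 0.0005     0.0055     TRUE
     ibuprofen normal   -2.9749       NA 0.0029     0.0346     TRUE
     meloxicam normal   -2.8949       NA 0.0038     0.0446     TRUE
      etodolac normal   -2.4440       NA 0.0145     0.1610    FALSE
           ...
```

Reading the output: `statistic` is the LR value (always ≥ 0) or the signed
z score — negative z means the drug's reports skew *female* relative to the
family background. `p_raw` is the per-table Monte-Carlo (LRT) or two-sided
normal p-value; `p_adjusted` is Max-Stat-adjusted, so `rejected = TRUE`
means the drug shows a family-wise-significant sex disparity at α = 0.05.
Four analgesics — acetaminophen (strongly female-skewed, |z| = 11.5),
aspirin (male-skewed, z = 3.5), ibuprofen and meloxicam — cross the
threshold; the other eight do not. LRT and normal-approximation results
agree closely, as they should for tables this large.

Operating characteristics can be checked on synthetic data:

```r
base <- generate_synthetic_base(n_aes = 60, seed = 11)
run_simulation(base, delta = 0, iterations_per_ae = 100, seed = 5)
```

which under the global null shows LRT/normal empirical FWER at or below
0.05 while PRR and ROR are inflated several-fold — the reason those two are
included for comparison rather than recommended.

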