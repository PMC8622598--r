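# cmax3 — covariate-adjusted MAX3 robust test for genetic association

Single-marker association tests for case-control studies must pick a
genetic model — recessive, additive or dominant — and picking wrong can
cost most of the power. The classical robust answer, the MAX3 test (the
maximum of the three model-specific trend statistics), works only on the
collapsed 2×3 phenotype-by-genotype table and therefore cannot adjust for
covariates such as age or sex; under covariate confounding it is not even
valid. `cmax3` implements the covariate-adjusted MAX3: the three
model-specific **score tests from logistic regression** with the
covariates profiled out, their maximum

&nbsp;&nbsp;&nbsp;&nbsp;T = max( |S(0)|, |S(1/2)|, |S(1)| ),&nbsp;&nbsp;&nbsp;&nbsp;S(z) = U(z)/√V(z),

and the asymptotic p-value P{ max |Y| > T } for Y ~ N(0, Σ), where Σ is
the estimated null correlation of the score triple. The package also
provides the 2-df genotype LRT and the covariate-free classical MAX3 as
comparators, a retrospective case-control simulation engine for
type-I-error and power studies, and single-SNP / batch / simulation
command-line entry points.

A structural point handled carefully here: Σ is *always* singular
(U(1/2) is exactly the average of U(0) and U(1)), so the "trivariate"
rectangle probability is really a degenerate 2-D problem. `mvn_rectangle()`
evaluates it by an exact rank-2 geometric reduction with deterministic
Gauss–Legendre quadrature — no Monte Carlo, no seed, and p-values far
below the genome-wide 5×10⁻⁸ threshold keep full relative precision. See
the methods vignette (`vignettes/cmax3-methods.Rmd`) for the model,
numerics and design decisions.

## Worked example

Simulate a retrospective 1:1 case-control cohort of 1000 subjects with a
dominant risk allele (MAF 0.3, effect 0.5 on the logit scale) and two
covariates, then test it:

```r
library(cmax3)
cfg <- sim_config(n = 1000, maf = 0.3, alpha = c(-5, 1, 0.5), beta = 0.5,
                  model = "DOM", seed = 42)
tab <- simulate_cohort(cfg)
cmax3_test(tab)
```

```
covariate-adjusted MAX3 test (n = 1000)
  statistic T = 3.0726, asymptotic p = 0.005128, best-fitting model: DOM
  S(REC) [z=0]: S =   0.8462, p = 0.3975
  S(ADD) [z=0.5]: S =   2.7388, p = 0.006166
  S(DOM) [z=1]: S =   3.0726, p = 0.002122
  LRT (2 df): stat = 9.4534, p = 0.008856
  null correlation of (S(0), S(1/2), S(1)):
       REC    ADD    DOM
REC 1.0000 0.6813 0.2881
ADD 0.6813 1.0000 0.8972
DOM 0.2881 0.8972 1.0000
```

Reading it: the dominant-model score statistic is the largest (T = 3.07,
best-fitting model DOM — correctly recovering the generating model). The
MAX3 p-value (0.0051) is slightly larger than the best single-model
p-value (0.0021) — the price of not knowing the model in advance — but
far better than having bet on the recessive model (p = 0.40), and smaller
than the 2-df LRT's (0.0089). The correlation matrix is the Σ used for
the p-value; note the strong ADD–DOM correlation typical at this allele
frequency.

The same analysis runs from a file in the layout
`phenotype genotype covariate...` (one row per subject):

```r
run_single("mydata.tsv")          # R API
```

```sh
inst/cli/cmax3 single mydata.tsv            # CLI
inst/cli/cmax3 batch --geno snps.tsv --pheno pheno.tsv --out results.tsv
inst/cli/cmax3 simulate --config cell.cfg --out rates.tsv
```

Batch mode fits the covariate-only null once, screens every SNP column,
and writes a table ordered by CMAX3 p-value with columns
`snp cmax3_p lrt_p s_rec_p s_add_p s_dom_p best_model note`.

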