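---
title: "Phytochelatin catalogs and accurate-mass annotation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phytochelatin catalogs and accurate-mass annotation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyctools)
```

## The problem

Phytochelatins (PyCs) are plant peptides built from repeating
γ-glutamyl-cysteine units, (γ-Glu-Cys)~n~-X, with n = 2–11 and a variable
C-terminal residue X. Their cysteine thiols chelate metals — essential
nutrients (Zn, Cu, Fe, Mn, Se) as well as toxicants (Cd, Hg, Pb, Ag, Ni,
Co) — and the peptides occur in multiple oxidation states (disulfide
bonds) and metal stoichiometries. In untargeted LC-MS metabolomics of
plant material these species appear as accurate-mass features, but no
hand-curated compound library can cover the combinatorial space.
`pyctools` takes the opposite route: the species space is defined by a
small set of construction rules, so the full catalog of elemental
formulas and monoisotopic masses is *generated*, deterministically, and
experimental masses are annotated against it.

## Construction rules

**Backbone and terminals.** The bare backbone of n condensed repeats is
C~8n~H~12n+2~N~2n~O~4n+1~S~n~; each terminal residue adds a fixed element
delta (Gly +C2H3NO, Ala +C3H5NO, Gln +C5H8N2O2, Ser +C3H5NO2, Glu
+C5H7NO3, or nothing). Ala and β-Ala are isomeric, hence one catalog
record carrying an alias — the catalog is a set of *formulas*, and
duplicate compositions would otherwise collide. Six
composition-distinct families × n = 2..11 give the base species.

**Disulfides.** Each S–S bond removes 2 H and consumes two cysteine
thiols; with n cysteines, up to min(⌊n/2⌋, 5) bonds are admitted (the cap
at five reflects the longest known chains).

**Metal binding.** Metals bind the ionized thiolate form; the formula
arithmetic removes the displaced thiol protons and adds the metal atom:
2 H per divalent ion (Cd, Co, Cu, Fe, Pb, Mn, Hg, Ni, Zn, and Ca, Mg),
1 H for Ag(1+). Selenium binds as a selenotrisulfide (–S–Se–S–),
formally divalent, so its arithmetic matches the divalents. Every bound
ion requires two *free* (non-disulfide) thiols, uniformly across metal
classes — so one ion needs n − 2m ≥ 2 and two ions need n − 2m ≥ 4. At
most two ions per peptide are enumerated; chemically, longer chains can
carry more, but evidence for such species is thin and the pair space is
already 91 unordered combinations of 13 metals.

**Bridges.** Every two-metal complex admits three bridged variants in
addition to the plain form, by analogy with bridging sulfurs in
iron–sulfur clusters: sulfido (+1 S), disulfido (+2 S) and selenido
(+1 Se). No mixed S+Se bridge and no diselenido form is generated.

These rules close exactly: per terminal family there are 40 metal-free
(terminal, n, m) scaffolds, 30 scaffolds that can hold one ion and 20
that can hold two, giving 6×40 = 240 metal-free species, 6×30×13 = 2 340
one-metal and 6×20×91×4 = 43 680 two-metal entries — 46 260 species with
pairwise distinct formulas:

```{r counts}
catalog <- enumerate_catalog()
summary(catalog)
```

The test suite checks this against an independent brute-force loop over
all (terminal, n, m, metal multiset, bridge) tuples filtered only by the
thiol rule.

## Masses and adducts

Monoisotopic masses are sums of NIST exact masses of each element's most
abundant isotope (e.g. ^114^Cd, ^202^Hg, ^80^Se), shipped as a versioned
CSV rounded to eight decimal places — never fetched at run time. Full
double precision is kept internally; printed values are rounded only at
I/O boundaries. Adduct m/z is (M + adduct mass)/z with the *proton* mass
(1.00727646 Da) as charge carrier — reference [M+H] values are only
reproduced by base mass + proton, not + neutral hydrogen atom. M+H,
M+2H and M+3H are registered by default; M+Na, M+K and M−H are available
but off.

A regression fixture of 35 species with literature-reported predicted
[M+H] values (base peptides of four families, one- and two-metal Hg, Cd,
Pb, Zn, Mn complexes, a disulfide form) must be reproduced at each
value's reported precision (4, 3 or 2 decimals):

```{r fixture}
ref <- reference_masses()
head(ref[, c("label", "expected_mz", "decimals")], 3)
all(vapply(seq_len(nrow(ref)), function(i)
  sprintf(paste0("%.", ref$decimals[i], "f"), predict_reference_mz(ref[i, ])) ==
  sprintf(paste0("%.", ref$decimals[i], "f"), ref$expected_mz[i]), logical(1)))
```

One fixture note: the species commonly reported as "PyC4-Gly-Hg"
(1202.1858) is, by its mass, the *single-disulfide* one-Hg complex; the
fixture stores it with `disulfides = 1` under the label
"(S-S)PyC4-Gly-Hg".

## Annotation model

A query m/z matches a (species, adduct) pair when
|10⁶·(q − t)/t| ≤ tolerance, with the theoretical m/z t as denominator.
The default tolerance is 5 ppm, typical for ultra-high-resolution
instruments. All species within tolerance are reported, ranked by |ppm|
per query — no best-hit collapsing and no confidence scoring; downstream
tools can add retention-time or isotope-pattern evidence. Reported ppm
deviations for literature comparisons are conventionally computed against
the theoretical m/z *at its printed 4-decimal precision*, which is how
the package's worked-example test treats them (at full precision the
third decimal of the ppm value can differ).

Optional filters restrict candidates before matching: terminal families,
repeat-count range, a metal subset (which keeps only complexes whose
bound ions all lie in the subset — pass `NULL` to keep metal-free species
too), and the NOPS element-ratio check. NOPS bounds the N/C, O/C, P/C
and S/C atom ratios by common-range heuristics for plausible organic
formulas (defaults 1.3, 1.2, 0.3, 0.8; configurable since published
threshold choices vary); carbon-free formulas fail closed, and bound
metals never enter a ratio.

## Synthetic query sets

`generate_query_set()` emulates the mass dimension of an LC-MS feature
table with known ground truth: it samples catalog species uniformly,
computes adduct m/z, and applies multiplicative Gaussian jitter in ppm —
the standard accurate-mass error model. Decoys are drawn uniformly over
the catalog's m/z range but rejected inside ±(3·jitter + guard) ppm of
any theoretical mass, so a search at a guard-consistent tolerance can
never annotate them; impossible placement (too dense a catalog for the
guard) raises an error rather than looping forever. Generation is fully
determined by the seed, and the caller's RNG state is restored.

What passing these tests shows — and does not. With 1 ppm jitter and a
5 ppm search, recall is essentially 1 (the normal 5σ tail is ~6×10⁻⁷)
and guarded decoys are never hit; the suite verifies both over several
seeds. Real feature tables additionally contain isotopologues, in-source
fragments, co-eluting isomers and intensity-dependent mass error — none
of which the generator simulates — so synthetic recall bounds the
matching machinery, not real-data annotation accuracy.

## Numerical and design choices

- Formulas are named integer count vectors; strings use Hill notation
  (C, H, then all other elements — metals included — alphabetically),
  with underscores and whitespace tolerated on input. Parse∘format is
  the identity.
- Chemically impossible arithmetic (negative element counts, binding
  without two free thiols per ion, bridges on fewer than two metals,
  disulfides beyond the cap) is rejected with the offending element or
  constraint named; during catalog enumeration the thiol rule silently
  *excludes* tuples instead, which is what makes the counts close.
- Catalog order is lexicographic in (terminal family, n, m, sorted metal
  pair, bridge), radix-sorted for locale independence; builds are
  byte-reproducible, and `write_catalog()` formats masses to 10 decimals
  so write → read → write is byte-identical.
- Problem sizes in the shipped tests: the full 46 260-species catalog is
  enumerated in well under a second (vectorized over element-count
  matrices), so tests and the acceptance script run it directly; the
  recall studies use 200 true queries × 5 seeds against family-restricted
  catalogs, ample for a tail probability of order 10⁻⁶ to show up as
  recall 1.
- The CLI (`build`, `annotate`, `fixtures`) is a thin wrapper over the
  same functions; logs go to stderr, results to files/stdout, so output
  is pipe-safe. Options mirror the R API; there is deliberately no
  separate config-file format.

## Limitations

Coordination geometry, binding affinity and kinetics are out of scope —
the catalog asserts which *formulas* are plausible, not which complexes
form under given conditions. Species with more than two bound ions,
mixed S+Se bridges, diselenido forms, alkali-metal (Na/K) complexes and
selenocysteine substitution are not generated. Annotation is by accurate
mass alone; identity confirmation needs orthogonal evidence (MS/MS,
retention time, isotope patterns).
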