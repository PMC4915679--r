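# orpscan

Microbial (type 1) opsins — bacteriorhodopsin-like proton pumps,
halorhodopsin chloride pumps and sensory rhodopsins — all photosense through
a retinal chromophore bound covalently to a conserved helix-7 lysine
(bacteriorhodopsin K216) via a Schiff base. A sizeable class of opsin
homologs in haloarchaeal (and some fungal) genomes lacks this lysine
entirely: the **opsin-related proteins (ORPs)**. They fall into two groups by
the residue replacing the Schiff-base lysine — arginine (**group A**) or a
hydrophobic residue such as leucine (**group B**) — have degraded
retinal-binding pockets but conserved signal-transduction residues, sit next
to methyl-accepting chemotaxis (HAMP/MCP) signal transducers, and occur in
genomes that often cannot even synthesize retinal (no *crtY*/*brp*). Together
this points to a family of sensory opsins responding to something other than
light.

`orpscan` is an R package (Bioconductor-style, S4) for running that screen on
any proteome:

- **Homology search** against a packaged opsin family panel (BR, BR2, HR,
  SRI, SRII, SR3, MR) with semi-global BLOSUM62 alignment and a
  decoy-calibrated profile-score gate standing in for a rhodopsin-domain
  scan (presets: *standard* = decoy mean + 4 SD, *strict* = + 6 SD).
- **Reference anchoring**: each hit is mapped onto sensory rhodopsin II
  residue numbering and fingerprinted at the positions that matter —
  signaling Y51, R72, D189, Y199; retinal pocket W76, V108, F127, W171,
  Y174, W178; Schiff-base K216.
- **Classification**: K at the Schiff column → canonical family (nearest
  reference by score); any other residue → ORP, with R → group A and a
  hydrophobic residue → group B; a gap → unassigned (truncation is not
  substitution).
- **Genome context** from GFF3: transducer-adjacent, taxis-operon-proximal,
  stress-proximal or unlinked, by keyword vocabulary and gene-rank rules.
- **Retinal-biosynthesis co-occurrence**: *crtY*, *brp*, *crtE*, *crtB*,
  *crtI* detection; retinal capability = *crtY* AND *brp*; cross-tabulation
  that isolates ORP-only genomes lacking the pathway.
- **Distance phylogenetics**: p/Poisson distances, neighbor joining, ORP
  monophyly test; Newick and iTOL `DATASET_BINARY` output.
- **Spectral calling**: retinal-bound vs apo decision from 250–800 nm
  absorbance spectra by integrated band prominence in the canonical
  480–580 nm window.
- **Synthetic data**: a seed-deterministic generator that plants opsins,
  ORPs with exact fingerprint edits, decoys, gene neighborhoods, pathway
  complements and spectra, with a complete truth table for validation.

The packaged reference panels are constructed synthetic exemplars (labelled
`*_synthetic.faa`) built so that SRII residue numbering holds literally;
swap in real family representatives via the `path` arguments of
`referencePanel()` / `crtPanel()` to screen real data.

## Worked example

Screen the default synthetic study (25 opsins across 9 classes, 10 decoys,
10 genomes with planted neighborhoods and pathway complements):

```r
library(orpscan)

bundle <- generateBundle(synthConfig(seed = 7))
screen <- runScreen(bundle$proteomes, bundle$features, outDir = "results/run1")
screen
#> OpsinScreen: 10 genome(s), 25 opsin homolog(s)
#>   ORPs: 8 (group A: 4 , group B: 4 , unassigned: 0 )
#>   transducer-adjacent: A = 3 , B = 1
#>   ORP-only genomes lacking crtY+brp: 3
```

All 35 planted protein labels, 8 ORP groups, 8 neighborhood categories and
10 pathway complements are recovered, and the ORP leaves form a
monophyletic clade in the NJ tree (`screenSummary(screen)$orpMonophyletic`).
The per-class conservation report reproduces the planted pocket erosion —
group A ORPs read D at position 76, L at 174, A at 178, R at the Schiff
column, with the transducer-contact Y199 intact:

```r
cons <- conservationTable(screen)
cons[cons$class == "ORP_A" & cons$position %in% c("76", "174", "178", "199", "216"), ]
#>    class position modal fraction n
#> 36 ORP_A       76     D        1 4
#> 40 ORP_A      174     L        1 4
#> 41 ORP_A      178     A        1 4
#> 43 ORP_A      199     Y        1 4
#> 44 ORP_A      216     R        1 4
```

Individual calls carry the nearest reference and alignment identity:

```r
head(as.data.frame(opsinCalls(screen))[, c("query", "family", "orpGroup", "nearestRef", "identity")], 5)
#>      query family orpGroup nearestRef  identity
#> 1 g01_g013     BR      n/a         BR 0.9521739
#> 2 g01_g038     HR      n/a         HR 0.9260870
#> 3 g01_g063    SR3      n/a        SR3 0.9565217
#> 4 g01_g088    ORP        A       SRII 0.8478261
#> 5 g02_g013     BR      n/a         BR 0.9608696
```

The report bundle under `results/run1/` holds the calls, fingerprint,
conservation, context and presence/absence tables (TSV), the iTOL binary
annotation, the Newick tree and a JSON summary logging every threshold.

Spectra are handled separately:

```r
s <- generateSpectrum(peakNm = 550, peakSd = 30, amplitude = 0.3, noiseSd = 0.005, seed = 1)
detectRetinalPeak(s)[c("bound", "lambdaMax")]
#> $bound
#> [1] TRUE
#> $lambdaMax
#> [1] 550
```

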