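# Bundled data

Small plain-text tables shipped with the package:

- `dtale1_offtarget_sites.tsv`, `dtale2_offtarget_sites.tsv` — reported
  genomic off-target 19-mers for the two designer TALEs characterized in
  rice (KitaakeX), with the positions flagged as mismatched against the
  respective binding element and the site location relative to the
  associated gene. Used as in-package test vectors.
- `published_offtarget_census.tsv` — reported number of genomic sites at
  1-4 mismatches from each binding element.
- `published_gene_categories_dtale1.tsv` / `_dtale2.tsv` — reported
  per-category gene counts near the off-target sites.

Reproducing the genome-wide census additionally requires the
*Oryza sativa* ssp. *japonica* cv. KitaakeX v3.0 genome assembly
(~380 Mb, available from Phytozome), which is not redistributed here.
Place it at `inst/extdata/OsativaKitaakeX_genome.fa` (or pass its path
directly to `scan_genome()` / `run_audit()`) to run that comparison.
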