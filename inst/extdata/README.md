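# Bundled fixtures

`toy_forward_hits.tsv` / `toy_reverse_hits.tsv` are hand-written BLAST
`-outfmt 6` tables for ten candidates (`c01`–`c10`) against two accepted
references (`REF1`, length 500; `REF2`, length 480) plus a decoy kinase
(`KINX`). With the documented thresholds (E ≤ 1e-28, coverage ≥ 0.80,
folded region 44–500 with ≤ 40 uncovered residues) each candidate probes
one filter boundary:

| candidate | construction | outcome |
|-----------|--------------|---------|
| c01 | unambiguously good | accepted |
| c02 | E-value 1e-20 | fails E-value screen |
| c03 | E-value exactly 1e-28 | accepted (cutoff is inclusive) |
| c04 | reverse best hit is KINX | fails reciprocal screen |
| c05 | reverse top score tied REF1/KINX | accepted (ties accept) |
| c06 | two HSPs 44–260 and 240–470; union 427/500 | accepted (HSPs pooled) |
| c07 | single span 1–399 (coverage 0.798) | fails coverage screen |
| c08 | span 85–500: 41 folded residues uncovered | fails folded screen |
| c09 | span 84–500: 40 folded residues uncovered | accepted (tolerance inclusive) |
| c10 | no reverse hit at all | fails reciprocal screen |

`toy_expected_accepted.txt` lists the accepted subset (c01, c03, c05,
c06, c09) and is asserted verbatim by the test suite.
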