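Place the eight deposited plastome records here as GenBank flat files,
named <accession>.gb:

  KC456163.gb  (Aralia undulata)
  KC456164.gb  (Brassaiopsis hainla)
  KC456167.gb  (Kalopanax septemlobus)
  KC456165.gb  (Metapanax delavayi)
  KC456166.gb  (Schefflera delavayi)
  JN637765.gb  (Eleutherococcus senticosus)
  AY582139.gb  (Panax ginseng)
  DQ898156.gb  (Daucus carota)

They are not shipped with the package (~1.5 MB of third-party data).
The third block of tests/testthat/test-acceptance.R runs against them
when present; an alternative directory can be given via
options(plastocomp.accession_dir = "...").
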