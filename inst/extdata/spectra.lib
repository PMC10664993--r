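# Spectrum library: one experiment per line.
# columns: name  kind  template  dims (comma list nucleus:role[:tol])  p_strong  p_weak
# kind: through-bond | noesy.  Default tolerances: 0.03 ppm (1H), 0.4 ppm (13C/15N).
N15HSQC    through-bond  N15HSQC    1H:amide-H,15N:amide-N               0.95  0.80
C13HSQC    through-bond  C13HSQC    1H:generic-H,13C:generic-C           0.95  0.80
HNCA       through-bond  HNCA       1H:amide-H,15N:amide-N,13C:aliphatic-C   0.95  0.80
HNcoCA     through-bond  HNcoCA     1H:amide-H,15N:amide-N,13C:aliphatic-C   0.95  0.80
HNCO       through-bond  HNCO       1H:amide-H,15N:amide-N,13C:carbonyl-C    0.95  0.80
HNcaCO     through-bond  HNcaCO     1H:amide-H,15N:amide-N,13C:carbonyl-C    0.95  0.80
CBCANH     through-bond  CBCANH     1H:amide-H,15N:amide-N,13C:aliphatic-C   0.95  0.80
CBCAcoNH   through-bond  CBCAcoNH   1H:amide-H,15N:amide-N,13C:aliphatic-C   0.95  0.80
HBHAcoNH   through-bond  HBHAcoNH   1H:amide-H,15N:amide-N,1H:aliphatic-H    0.95  0.80
hCcoNH     through-bond  hCcoNH     1H:amide-H,15N:amide-N,13C:aliphatic-C   0.95  0.80
HCCHTOCSY  through-bond  HCCHTOCSY  1H:generic-H,13C:generic-C,1H:generic-H  0.95  0.80
CCHTOCSY   through-bond  CCHTOCSY   13C:generic-C,13C:generic-C,1H:generic-H 0.95  0.80
N15NOESY   noesy         N15NOESY   1H:generic-H,15N:amide-N,1H:amide-H      -     -
C13NOESY   noesy         C13NOESY   1H:generic-H,13C:generic-C,1H:generic-H  -     -
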