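# Built-in RNA 3D motif descriptor library.
#
# Format: CLASS NAME key=value ...   ('#' comments; empty value = empty segment)
#   HL : Loop + correlated L1..Lk / R1..Rk     (hairpin loop motifs)
#   BL : Loop + optional correlated L/R pairs  (bulge motifs)
#   IL : Lo Loop1 Li  Ri Loop2 Ro              (internal loop motifs)
#   J3 : S1 S2 S3                              (three-way junction motifs)
#   J4 : S1 S2 S3 S4                           (four-way junction motifs)
#   BS : S1                                    (branch segment motifs)
#
# Consensus provenance:
#   GNRA       L='G', Loop='N', R='RA' (G pairs with both R and A)
#   UNCG       tetraloop UNCG: U correlated with G, loop 'NC'
#   U-turn     three-residue loop 'URA'; no correlated flanks
#   K-turn     correlated G.A/A.G stem steps; 3-nt strand consensus 'RNN',
#              opposite strand empty
#   loop-E     five consensus positions on each branch (bacterial loop E /
#              sarcin-ricin core; branch consensus curated here)
#   C-loop     curated consensus of the C-loop internal motif
#   hammerhead J3 junction with the conserved catalytic boxes (CUGANGA, GAAA)
#   J3-groupII branches (5'-3') 'A', 'RAA' and empty
#   J4-generic all-empty branches (coaxially stacked four-way junction)
#   CsrA       GGA binding site presented as a branch-segment motif

HL GNRA        L1=G Loop=N R1=RA
HL UNCG        L1=U Loop=NC R1=G
HL U-turn      L1= Loop=URA R1=
IL K-turn      Lo= Loop1= Li=GA Ri=AG Loop2=RNN Ro=
IL loop-E      Lo= Loop1=AGUAC Li= Ri= Loop2=GAUGG Ro=
IL C-loop      Lo= Loop1=CAC Li= Ri= Loop2=ACAG Ro=
J3 hammerhead  S1=CUGANGA S2=GAAA S3=
J3 groupII     S1=A S2=RAA S3=
J4 generic4    S1= S2= S3= S4=
BS CsrA        S1=GGA
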