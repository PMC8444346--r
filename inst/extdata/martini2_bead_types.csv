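# Martini 2 bead-type reference table.
# dgow_kj: per-bead reference octanol-water transfer free energy (kJ/mol,
#   water->octanol; hydrophobic types negative).  The ladder follows the
#   polarity ordering of the Martini 2 force field (Marrink et al.,
#   J. Phys. Chem. B 2007, 111, 7812), with the absolute per-bead scale
#   anchored so that benzene is matched by an N0 trimer and a C5 dimer.
# hbond: hydrogen-bonding class; window_only: selectable only through the
#   Nda hydrogen-bond window, not by the distance rule.
type,dgow_kj,hbond,charge,window_only
P5,9.00,none,0,FALSE
P4,6.50,none,0,FALSE
P3,4.50,none,0,FALSE
P2,3.00,none,0,FALSE
P1,1.50,none,0,FALSE
Nda,0.00,da,0,FALSE
Nd,0.00,d,0,TRUE
Na,0.00,a,0,TRUE
N0,-4.08,none,0,FALSE
C5,-6.10,none,0,FALSE
C4,-8.00,none,0,FALSE
C3,-10.50,none,0,FALSE
C2,-13.50,none,0,FALSE
C1,-17.00,none,0,FALSE
Q0,NA,none,1,FALSE
Qa,NA,a,1,FALSE
Qd,NA,d,1,FALSE
Qda,NA,da,1,FALSE
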