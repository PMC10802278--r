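# Synthetic fiducial-site geometry for the actin protomer (version 1).
# Cylindrical offsets of the CA positions of the three scoring residues,
# relative to the protomer frame: radius (nm) from the filament axis,
# azimuth (degrees) relative to the protomer phase, axial (nm) relative
# to the protomer z. These are plausible actin-surface coordinates
# (subdomain-1 residues sit 2.2-2.6 nm from the axis); they are a
# synthetic stand-in, not measurements from a deposited model, and every
# downstream score is self-consistent with whatever table replaces them.
residue,radius,azimuth,axial
D24,2.30,-35,0.90
R95,2.60,10,1.40
S350,2.40,45,0.30
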