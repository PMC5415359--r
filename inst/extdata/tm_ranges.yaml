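# Shipped TM-helix Calpha residue ranges (author numbering) used for RMSD
# selections.  These ranges are the package's versioned defaults:
# approximate helix assignments, made explicit here because no single
# authoritative table exists.  Override per run via the config.
trek2:          # human TREK-2, crystal construct residues 67-340
  - [72, 102]   # M1
  - [186, 228]  # M2
  - [234, 264]  # M3
  - [302, 340]  # M4
twik1:          # human TWIK-1 (non-mechanosensitive control)
  - [19, 47]    # M1
  - [145, 175]  # M2
  - [184, 212]  # M3
  - [246, 277]  # M4
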