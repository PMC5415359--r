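# k2pflex default run configuration (versioned defaults; every analysis
# parameter in any output is traceable to this file or a user override).

seed: 1

# --- inputs (set by the user config) ---------------------------------------
topology: null        # PDB topology
trajectory: null      # .xyzb / .dcd trajectory
down_ref: null        # down-state reference PDB
up_ref: null          # up-state reference PDB

# --- selections -------------------------------------------------------------
# TM helix Calpha ranges used for RMSD (author residue numbering).
# See tm_ranges.yaml for the shipped per-channel table.
tm_ranges:
  - [72, 102]    # M1
  - [186, 228]   # M2
  - [234, 264]   # M3
  - [302, 340]   # M4

gating:
  atom: CA
  partner_map: {A: B, B: A}

phosphate_name: PH
ion_name: K
water_resname: HOH
lipid_head_names: [PH]   # lipid tails = lipid heavy atoms excluding these

# --- numeric parameters ------------------------------------------------------
slice_thickness: 1.0     # Angstrom, area-profile z slice
raster: 0.25             # Angstrom, area-profile xy raster
bin_width_nm: 0.1        # pressure-profile z grid
margin: 0.5              # Angstrom, state-classification margin
stride_ps: 1000          # landscape sampling stride (1 ns)
smooth_ps: 5000          # event-detection smoothing window
dwell_ps: 10000          # event-detection dwell requirement
contact_threshold: 4.0   # Angstrom, lipid "bound" threshold
dewetting_threshold: 5   # waters; dry if count < threshold
dewetting_min_duration: 1  # frames

# --- filter sites (synthetic defaults; derive from carbonyl planes for
#     real structures with filter_sites_from_planes) ------------------------
filter_sites:
  S0: {zmin: 13, zmax: 16}
  S1: {zmin: 10, zmax: 13}
  S2: {zmin: 7, zmax: 10}
  S3: {zmin: 4, zmax: 7}
  S4: {zmin: 1, zmax: 4}

n_lipids_per_leaflet: null
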