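# levatorfem default run configuration
# Units: mm, MPa, N; density in kg/l; angles in degrees; stations in cm.

material:
  # two-term Ogden set identified for passive levator ani muscle
  # (cadaver uniaxial tension, least-squares fit)
  mu: [8.0e-5, 1.7e-4]        # MPa
  alpha: [1.81, 17.25]        # dimensionless
  poisson: 0.499              # near-incompressible soft tissue
  density_kg_l: 1.06          # mammalian skeletal muscle

geometry:
  head:                       # 50th-percentile term fetal head diameters, mm
    suboccipitobregmatic: 100.3
    occipitofrontal: 105.7
    occipitomental: 131.9
    biparietal: 93.7
  pelvis:                     # gynecoid bony pelvis diameters, mm
    inlet_ap: 113.4
    outlet_ap: 145.1
    transverse_inlet: 148.8
    interspinous: 146.7
  levator:                    # synthetic shell calibration (see vignette)
    shell_thickness: 7        # mm
    hiatus_width: 35          # mm, urogenital hiatus
    hiatus_length: 55         # mm
    mesh_edge: 6              # mm target element edge (4 / 2 for fine runs)
  head_mesh_edge: 4           # mm
  pelvis_mesh_edge: 6         # mm

trajectory:
  start_station: -3           # engagement
  end_station: 5              # vertex at +5 before extension
  frames_per_station: 5
  carus_radius: 160           # mm, curve-of-Carus arc
  total_anterior_mm: 100.0    # net anterior displacement of the head origin
  extension_deg: 80.25
  lateral_deviation_deg: 28.66  # initial rightward deviation, straightened
  internal_rotation_deg: 40.13  # occiput left-anterior to anterior
  rotation_complete_station: 3
  extension_frames: 24
  extension_caudal_mm: 8      # drift keeping the vertex descent monotone
  extension_pivot_y: 65       # inferior pubic margin (extension hinge), mm
  extension_pivot_z: -35
  start_anterior_mm: 0

solver:
  tether_stiffness: 0.5       # N/mm, tendinous-arch support springs
  # remaining solver settings take package defaults; override here, e.g.
  # newton_tol: 1.0e-6
  # search_radius: 10

output:
  dir: levatorfem_results

seed: 1
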