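# Central vertebral-body injection experiment.
# Elliptical-cylinder phantom, oil injected at the physical center;
# observation planes 1/2/3 (transverse, z = 0, +2, -2 mm) and 6/5/7
# (longitudinal, y = 0, +5, -5 mm). Snapshots at 1, 4, 7 s.
phantom:
  type: body_center
  a_x: 0.021            # transverse interior semiaxis (m)
  a_y: 0.015            # anteroposterior interior semiaxis (m)
  half_height: 0.010    # interior half-height (m)
  shell_thickness: 0.001
  porosity: 0.75
  pore_diameter: 0.0009 # mean pore diameter (m); Kozeny-Carman permeability
fluids:
  oil_cSt: 100000       # silicone oil kinematic viscosity (cSt)
  rho_oil: 970          # kg/m^3
  mu_air: 1.8e-5        # Pa s
  rho_air: 1.2
injection:
  rate: 3.0e-7          # m^3/s (0.3 mL/s)
  duration: 7           # s
  output_times: [1, 4, 7]
numerics:
  h: 0.0005             # voxel edge (m)
  cfl: 0.5
  tol: 1.0e-10
  pressure_lag: 1
  transport: implicit
  gravity: false
metrics:
  theta: 0.5
output:
  dir: runs/body_center
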