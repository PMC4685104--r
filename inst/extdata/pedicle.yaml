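# Pedicle-junction injection experiment.
# Body phantom plus a cancellous pedicle channel through the posterolateral
# shell; injection at the pedicle-body junction (coordinate origin). The
# upper endplate interior surface sits at z = +10 mm, plane 4 at z = 9.7 mm
# (0.3 mm below it); lateral and posterior wall rings surround the injection
# point. Snapshots every second.
phantom:
  type: pedicle_junction
  a_x: 0.021
  a_y: 0.015
  half_height: 0.010
  shell_thickness: 0.001
  porosity: 0.75
  pore_diameter: 0.0009
  pedicle_radius: 0.0025
  pedicle_length: 0.005
  pedicle_offset_x: 0.012
fluids:
  oil_cSt: 100000
  rho_oil: 970
  mu_air: 1.8e-5
  rho_air: 1.2
injection:
  rate: 3.0e-7
  duration: 7
  output_times: [1, 2, 3, 4, 5, 6, 7]
numerics:
  h: 0.0005
  cfl: 0.5
  tol: 1.0e-10
  pressure_lag: 1
  transport: implicit
  gravity: false
metrics:
  theta: 0.5
output:
  dir: runs/pedicle
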