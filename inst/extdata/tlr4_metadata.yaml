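# Metadata sidecar for the TLR4 early-sepsis Boolean network.
# Delays are in simulation time steps.  Node classes are editable; the
# loader checks them against expected_class_counts when that key is present.

delays:
  B_CL: 2
  Phag_L: 2
  Apop: 2
  T_MAC: 2
  T_TF: 2
  Phag_E: 1
  Anti_inflam: 3

classes:
  pathogen: [Infection, Bacteria, LPS]
  host_cell: [Act-Mon, Act-Mac, Mac-M1, Mac-M2, Act-DC, Act-Neu, Act-NK,
              Act-EC, Act-PLT, CD4T, CD8T, Treg, Bcell]
  mediator: [ICAM-1, VCAM-1, E-selectin, NETs, TF, C3b, C5a, C5b, ROS,
             TNF-a, IL-1B, IFN-gamma, IL-6, IL-8, IL-12, IL-18, IL-10,
             sTNF-R, IL-1Ra]
  outcome: [Phagocytosis, MAC, Thrombosis, Ang2]
  other: [TLR4, Apoptosis, P-selectin]

expected_class_counts:
  pathogen: 3
  host_cell: 13
  mediator: 19
  outcome: 4
  other: 3

# Simulations start at the onset of infection: only Infection is active.
initial_state:
  Infection: 1

endpoints: [Phagocytosis, MAC, Thrombosis, Ang2]

# Direction of benefit per endpoint: thrombosis and angiopoietin-2 track
# organ damage (a decrease is beneficial), phagocytosis and the membrane
# attack complex track bacterial clearance (an increase is beneficial).
endpoint_direction:
  Phagocytosis: increase
  MAC: increase
  Thrombosis: decrease
  Ang2: decrease

# Nodes perturbed in the treatment-target screens: the mediator molecules
# plus the TLR4 receptor itself, which is a druggable upstream target.
# NETs (an extracellular chromatin structure rather than a secreted
# molecule, and a direct structural AND-input of the Thrombosis rule) is
# not part of the screen.
screen_set: [ICAM-1, VCAM-1, E-selectin, TF, C3b, C5a, C5b, ROS,
             TNF-a, IL-1B, IFN-gamma, IL-6, IL-8, IL-12, IL-18, IL-10,
             sTNF-R, IL-1Ra, TLR4]
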