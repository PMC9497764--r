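l0_skin,l0_depth,l1_skin,l1_depth,l2_skin,l2_depth,l3_skin,l3_depth,l4_skin,l4_depth,l5_skin,l5_depth,l6_skin,l6_depth,l7_skin,l7_depth,l8_skin,l8_depth,l9_skin,l9_depth,r0_skin,r0_depth,r1_skin,r1_depth,r2_skin,r2_depth,r3_skin,r3_depth,r4_skin,r4_depth,r5_skin,r5_depth,r6_skin,r6_depth,r7_skin,r7_depth,r8_skin,r8_depth,r9_skin,r9_depth,t1_skin,t1_depth,t2_skin,t2_depth,risk
33.51,36.19,33.7,36.95,32.99,36.35,33.81,36.27,33.25,36.18,34.03,36.28,33.22,35.94,34.38,37.79,34.47,38.63,33.95,38.07,33.42,36.18,34.19,37.07,33.06,36.32,33.86,36.33,33.23,36.28,34.19,36.57,32.92,35.99,33.57,36.34,33.56,37.02,33.23,36.37,33.05,37.14,33.95,36.3,1
34.35,36.67,33.77,36.55,33.27,36.99,33.83,36.57,32.74,36.42,33.36,36.09,34.89,38.08,34.23,37.31,34.35,38.01,33.51,37,34.13,36.55,33.64,36.58,33.23,36.87,33.73,36.55,32.71,36.25,33.42,36.21,34.29,36.62,33.66,36.09,33.5,36.5,33.37,37.04,33.88,36.37,33.53,36.23,1
34.22,36.71,34.17,37.68,33.72,36.98,33.65,36.78,33.28,36.92,33.69,36.31,34.4,36.53,33.71,37,32.9,36.65,34.91,38.36,33.31,35.38,33.59,36.36,33.84,36.89,33.71,36.41,33.18,36.8,33.57,36.36,34.46,36.42,33.74,36.95,32.8,36.82,34.18,36.74,33.28,37.07,33.03,36.93,1
33.58,35.85,32.95,36.69,33.98,36.43,33.87,35.54,33.48,36.9,33.66,37.05,33.61,37.11,33.7,36.68,33.07,35.68,33.22,36.57,33.83,35.86,32.73,36.64,34.28,36.33,33.85,35.5,33.52,37.01,33.93,37.03,33.55,37.28,33.58,36.88,33.21,35.6,32.83,36.42,33.58,36.23,33.07,36.52,0
33.91,36.86,34.18,36.58,33.91,36.23,33.62,36.32,33.57,37.07,34.07,36.27,33.59,36.78,33.31,36.18,33.73,36.11,33.74,37.35,33.93,36.87,33.98,36.37,33.78,36.23,33.49,36.33,33.7,36.86,34.25,36.4,33.44,36.56,33.32,36.19,33.75,36.13,33.66,37.11,33.18,36.45,33.05,36.49,0
33.8,36.17,33.21,36.79,34.02,36.98,33.98,36.66,33.35,36.37,33.52,37.03,33.69,36.91,33.58,37.13,34.14,36.37,33.44,35.94,34.48,37.27,34.01,38.13,33.81,36.82,34.19,36.61,33.59,36.48,33.52,36.83,34.07,36.67,33.59,37.22,34.17,36.21,34.25,37.24,33.58,36.63,33.94,36.7,1
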