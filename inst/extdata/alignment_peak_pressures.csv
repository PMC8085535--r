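label,P1,P2
Reference configuration,2.93,6.22
Varus tilt 1 deg,2.88,7.83
Varus tilt 3 deg,2.69,7.00
Varus tilt 5 deg,3.14,10.10
Valgus tilt 1 deg,2.78,6.01
Valgus tilt 3 deg,2.73,5.49
Valgus tilt 5 deg,2.68,4.72
Internal rotation 1 deg,3.87,7.14
Internal rotation 5 deg,8.98,14.50
External rotation 1 deg,2.96,6.25
External rotation 5 deg,4.92,8.39
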