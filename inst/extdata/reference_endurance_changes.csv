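axis_sensor,set2,set3,set4,set5,avg_printed
x_gyroscope,0.7,1.2,-6.3,-5.2,-2.4
z_gyroscope,0.5,1.7,-10.4,-7.5,-3.9
y_accelerometer,0.6,0.3,0.3,0.4,0.4
per_set_average,0.6,1.1,-5.5,-4.1,NA
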