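axis_sensor,set2,set3,set4,set5,avg_printed
x_gyroscope,2.0,6.0,17.0,33.0,14.5
z_gyroscope,1.7,11.0,15.0,45.0,18.2
y_accelerometer,1.5,7.4,11.0,15.0,8.7
per_set_average,1.7,8.1,14.3,31.0,NA
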