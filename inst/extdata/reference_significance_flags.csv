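feature,signal,statistic,sig_fatigue,sig_complete
gyr_x_mean,gyr_x,mean,FALSE,FALSE
gyr_x_sd,gyr_x,sd,FALSE,FALSE
gyr_x_aad,gyr_x,aad,FALSE,FALSE
gyr_y_mean,gyr_y,mean,TRUE,TRUE
gyr_y_sd,gyr_y,sd,FALSE,TRUE
gyr_y_aad,gyr_y,aad,TRUE,FALSE
gyr_z_mean,gyr_z,mean,TRUE,TRUE
gyr_z_sd,gyr_z,sd,TRUE,TRUE
gyr_z_aad,gyr_z,aad,TRUE,FALSE
mag_x_mean,mag_x,mean,FALSE,FALSE
mag_x_sd,mag_x,sd,FALSE,FALSE
mag_x_aad,mag_x,aad,FALSE,FALSE
mag_y_mean,mag_y,mean,FALSE,FALSE
mag_y_sd,mag_y,sd,TRUE,FALSE
mag_y_aad,mag_y,aad,FALSE,FALSE
mag_z_mean,mag_z,mean,FALSE,FALSE
mag_z_sd,mag_z,sd,FALSE,TRUE
mag_z_aad,mag_z,aad,TRUE,TRUE
acc_x_mean,acc_x,mean,TRUE,FALSE
acc_x_sd,acc_x,sd,TRUE,FALSE
acc_x_aad,acc_x,aad,TRUE,FALSE
acc_y_mean,acc_y,mean,TRUE,TRUE
acc_y_sd,acc_y,sd,TRUE,TRUE
acc_y_aad,acc_y,aad,TRUE,TRUE
acc_z_mean,acc_z,mean,TRUE,TRUE
acc_z_sd,acc_z,sd,TRUE,TRUE
acc_z_aad,acc_z,aad,TRUE,TRUE
total_acceleration_mean,total_acceleration,mean,TRUE,TRUE
total_acceleration_sd,total_acceleration,sd,TRUE,TRUE
total_acceleration_aad,total_acceleration,aad,TRUE,TRUE
exerted_force_mean,exerted_force,mean,TRUE,TRUE
exerted_force_sd,exerted_force,sd,TRUE,TRUE
exerted_force_aad,exerted_force,aad,TRUE,TRUE
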